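---
title: "Detecting and quantifying resting-state reactivation in cortical calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying resting-state reactivation in cortical calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restreact)
```

## The scientific problem

During quiet wakefulness after a spatial experience, cortical populations
spontaneously re-express activity patterns from that experience. In
head-fixed mice running a 150 cm cued treadmill belt, two kinds of
representations coexist in secondary motor cortex: place-cell-like activity
tiling the belt, and responses locked to the visuo-tactile cues mounted on
it. `restreact` implements a complete analysis chain for asking how these
two representations reactivate offline: which neurons are spatially
selective, which groups of neurons co-activate synchronously during rest,
whether each such ensemble encodes a cue or a short trajectory segment,
how strongly and when each ensemble reactivates, and how those
reactivations are timed relative to hippocampal sharp-wave ripples (SWRs).

Because real sessions are large and external, the package ships a
synthetic-session generator with planted ground truth. Every stage of the
pipeline is validated by parameter recovery: the generator plants cells,
ensembles, reactivation times, SWRs and class-specific lags, and the test
suite checks that the analysis recovers them.

## The analysis chain and its models

### Spatial tuning and place fields

The belt is divided into $N = 50$ bins of 3 cm. A neuron's tuning curve is
the occupancy-weighted mean of its deconvolved activity per bin, and its
spatial information is

$$I = \sum_{i=1}^{N} p_i \frac{f_i}{f} \log_2 \frac{f_i}{f},$$

with $f_i$ the mean activity in bin $i$, $p_i$ the occupancy fraction and
$f$ the overall mean. Significance is assessed against a circular-shuffle
null: the activity trace is rotated by a random offset (at least 1 s, so
the null stays conservative) and $I$ recomputed; a neuron passes when its
information exceeds the 95th percentile of 1,000 shuffles. Unvisited bins
are excluded from the sum rather than imputed.

Place fields are found by a continuous wavelet transform of the tuning
curve with a Ricker (Mexican-hat) wavelet at integer scales 1–50. The
curve is treated as circular — the belt is a loop, and wrapping avoids
edge artifacts at the reward line. Local coefficient maxima exceeding
3 median absolute deviations above the median of the scale-1 coefficients
are candidates. Overlapping candidates are resolved in decreasing order of
coefficient: a candidate whose centre falls inside an already-accepted
field's bounds (or vice versa) is discarded. We resolve by dominant
response rather than by scale because a strict larger-scale-wins rule lets
a weak, broad response centred between two distinct bumps absorb both — on
twin Gaussian bumps the blend maximum sits at their circular midpoint and
would otherwise erase two genuine fields. A field's width is the distance
between the Ricker zero-crossings at the detected scale ($2\sigma$ bins);
fields must span 5–80% of the belt, have in-field mean activity at least
2.5× the out-of-field mean, and contain the per-lap activity peak on at
least a third of laps. Sessions with fewer than 10 laps are excluded
outright. A neuron is spatially selective when it passes both the shuffle
test and supports at least one valid field.

### Synchronous ensembles

Rest traces are Gaussian smoothed ($\sigma$ = 200 ms) to absorb temporal
jitter, movement epochs are removed, and the pairwise Pearson correlation
$r$ of the z-scored traces is converted to the distance $d = 1 - r$.
Average-linkage (UPGMA) agglomerative clustering is cut at $d = 0.75$,
i.e. a mean within-cluster correlation of 0.25, and clusters with at least
5 members are ensembles.

Each ensemble is then labelled from the spatial content of its members.
Each spatially-selective member's trial-averaged tuning curve is min–max
normalized; the stretches of belt where any member exceeds 0.5 are the
candidate segments (circularly wrapped across the reward line, and
requiring support from at least 3 spatially-selective cells — the 0.5
threshold is applied per member, following the "any ensemble neuron"
reading; ensembles with fewer than 3 spatial members are not considered).
A segment shorter than 30 cm that spans a cue centre (inclusive endpoints,
strict containment of the centre point) makes the ensemble a *cue*
ensemble; otherwise any remaining segment makes it a *trajectory*
ensemble; otherwise it stays unclassified. When both a qualifying cue
segment and longer segments exist, cue wins — the rule is lexically
cue-first. Composition bias of spatial cells within an ensemble is scored
by an upper-tail hypergeometric test.

A per-neuron encoding bias compares two maximum-likelihood models of the
binned RUN activity under a Poisson observation law (the natural choice
for deconvolved event rates on 3 cm bins): a Gaussian spatial tuning
(baseline, amplitude, centre, width; circular distance; fitted by bounded
optimization with a multi-start over the centre) versus a distinct rate at
each cue location plus constant baseline (closed-form MLE). The
log-likelihood ratio is positive for cue-like, negative for place-like
cells.

### Seeded PCA–ICA reactivation model

`fit_reactivation()` is the package's central estimator. The ensembles
seed a basis $\widetilde{W}$ whose column $m$ is the unit-normalized
membership indicator (nonzeros $1/\sqrt{|m|}$); disjoint memberships make
$\widetilde{W}^\top \widetilde{W} = I$. The rest activity is standardized
per neuron (mean 0, variance 1, on non-movement frames; these statistics
are stored and reused when projecting RUN or other blocks, so all blocks
live in the same component space). The seed-explained variance is
subtracted, $\hat{X} = X - X \widetilde{W} \widetilde{W}^\top$, and the
residual is screened for additional structure: eigenvectors of the
residual's second-moment matrix whose eigenvalues exceed the
Marčenko–Pastur upper bound $\lambda_+ = (1 + \sqrt{N/T})^2$ are retained.
We decompose the covariance (cross-product) of the standardized residual
rather than its correlation because only the covariance eigenvectors are
exactly orthogonal to $\widetilde{W}$, which the orthonormality of the
concatenated basis $\widetilde{W}' = (\widetilde{W} \mid \Sigma_{\lambda_+})$
requires (asserted to $10^{-8}$ in the tests); a correlation option is
provided.

The data are projected onto $\widetilde{W}'$, pre-scaled to unit column
variance so the sparsity penalty has a data-independent scale, and refined
by reconstruction ICA: minimize over the rotation $W$

$$\frac{1}{T}\sum_i \lVert x_i - x_i W W^\top \rVert_2^2
  + \frac{\beta}{T} \sum_i \sum_j g(x_i W_j), \qquad
  g(x) = \tfrac{1}{2}\log\cosh(2x),$$

by gradient descent with backtracking line search from $W = I$ (the
natural start once the data are in the estimate's basis; the fit is
deterministic). Both terms are averaged over rows so their balance does
not drift with the block length, and the penalty weight $\beta$ defaults
to 1 with a configurable override. Convergence is a relative objective
change below $10^{-6}$ within 500 iterations; non-convergence returns the
best iterate with a flag. The first $M$ columns of $\widetilde{W}' W^\top$
are the final components, sign-flipped so the dominant weight is positive
and renormalized to unit length.

Projecting any standardized block onto the components gives each
ensemble's reactivation strength over time. Events are excursions above
$\mu + 3\sigma$ of the strength, with onset/offset pushed outward to 25%
of that threshold; extended events that overlap are merged. Projecting the
RUN block and averaging each ensemble's strength per spatial bin gives the
ensemble's *reactivated feature*, a 50-bin spatial profile.

### Sharp-wave ripples

LFP (analysed at 2.6 kHz) is band-pass filtered 150–250 Hz with a
400-order FIR filter applied forward–backward (zero phase), and an RMS
envelope is extracted with an 8 ms sliding window. Regions above
$\mu + 3\sigma$ of the envelope are ripple cores; cores must sustain the
threshold for at least 3 ripple cycles (15 ms at the 200 Hz band centre by
default, with an optional literal zero-crossing cycle counter), with
sub-cycle dips bridged. We apply the duration rule to the core rather than
to the extended bounds: on pure pink noise the extended-bounds reading
admits hundreds of false events per 10 minutes, while the core reading
admits about one. Surviving events are extended to the crossings of 75% of
the threshold, and an event starting within 250 ms of the previous onset
is merged into it (a pure-discard option exists). All thresholds are
SD-relative, so detection is invariant to the recording gain.

### Timing, coupling and pattern completion

Peri-SWR averages z-score each ensemble's strength and average windows
around SWR onsets. Lags between the cue-class and trajectory-class
averages are estimated by unbiased-normalized cross-correlation with a
four-parameter Gaussian fitted to the coefficient curve (the fitted mean
is the lag; fit failure falls back to the argmax with a flag). Because the
resonant-galvo scanner sweeps the field of view within each ~50 ms frame,
any imaging-derived lag carries an irreducible ±dwell/3 ≈ ±17 ms bound,
which is reported alongside the frame period.

Cue–trajectory ensemble pairs are called *coupled* when the peak absolute
cross-correlation of their strength series within ±1 s exceeds the
one-tailed 95% bound of a circular-shift surrogate null (at least 500
shifts of at least 1 s; circular shifts preserve each series'
autocorrelation while destroying their alignment, which is exactly the
structure the test must be blind to). A pair's lag is the mean lag weighted by the positive
part of the correlation curve. Feature similarity between the members of
a pair is the Pearson correlation of their 50-bin reactivated features
(Fisher-transformed for group statistics). The fraction of reactivation
events associated with an SWR uses an onset-within-±500 ms window by
default — the association window is not pinned down by the source
analyses, so it is exposed as a parameter and reported with results.

Explained variance (ev) asks how much of the RUN pairwise-correlation
structure reappears in post-task rest beyond what pre-task rest already
had: the squared partial correlation of the upper-triangle correlation
vectors of (RUN, REST2) controlling REST1, as a percentage; rev swaps the
rest epochs and serves as the control. Ensemble persistence between rest
blocks uses the Jaccard index $J = O/(A + B - O)$ (maximum over paired
comparisons), with significance from a one-tailed Fisher exact test at
$\alpha = 0.001$.

Finally, the Hopfield experiment tests whether a cue ensemble's
reactivated feature can retrieve the trajectory feature it is temporally
coupled with. Features are binarized to ±1 at half of their normalized
range (configurable), and patterns live in the 50-bin feature space —
features, not raw population vectors, are what the coupling analysis
produces. Two trajectory features — one coupled to the probing cue,
one not — are stored by the Hebbian outer-product rule (symmetric weights,
zero diagonal); the cue feature is presented as a partial probe and
relaxed by asynchronous sign updates in fixed index order (ties keep the
current bit), which makes the energy non-increasing. Retrieval succeeds
when the settled state is nearer in Hamming distance to the coupled
trajectory pattern; equidistant outcomes are reported as indeterminate.

## The synthetic-session generator

`simulate_full_experiment()` builds a REST1/RUN/REST2 session at ~19 Hz
with, by default, 100 neurons (35% place cells, 10% cue cells), a 150 cm
belt with four cues (the last two close together, as on the physical
belt), 8 min of running at ~15 cm/s with a 1 s reward pause per lap
(guaranteeing the ≥10-lap inclusion rule), and 10 min rest blocks. Place
cells have Gaussian tuning (σ = 8 cm); cue cells respond within the cue
footprint at every cue. Three ensembles are planted by default — one cue
ensemble drawn from the cue cells and two trajectory ensembles whose
members' fields tile a contiguous 30–40 cm segment — with 6–10 members
each. REST2 expresses all ensembles and REST1 only one, matching the
sparser pre-task rest. Reactivation events are ~180 ms half-Gaussian
transients in all members simultaneously (the median event duration the
detector targets), at about twice the amplitude of background transients
so that ensembles are as conspicuous as in real recordings, with ±20%
per-member amplitude jitter so the ICA weighting is non-degenerate.
Background activity is independent sparse transients at 0.1 Hz per neuron
plus truncated Gaussian noise; the background statistics during rest are
not constrained by any published value, so they are exposed in the
configuration rather than fixed. A configurable fraction (8%) of rest
frames is flagged as movement and excluded downstream.

SWRs are planted as ~50 ms amplitude-modulated 200 Hz bursts on a
pink-noise LFP at 2.6 kHz, scaled so the ripple-band envelope clears the
configured SD level above background regardless of the background phase
(random phase interference otherwise spreads realized burst amplitudes by
several SDs and would make "a 5 SD burst" ill-defined). A configurable
fraction of reactivation events is time-locked to SWR onsets, cue
ensembles at a 50 ms lag and trajectory ensembles at 180 ms by default, so
lag estimators can be validated against a planted 130 ms difference.

What the generator does *not* emulate: biophysical calcium dynamics and
deconvolution artifacts (the pipeline consumes deconvolved rates
directly, and an analysis of raw fluorescence would need its own model),
motion and neuropil contamination, ROI segmentation errors, across-day
field-of-view drift, and any dependence of ensemble membership on
behavioural variables beyond position. Passing recovery tests on these
sessions therefore shows the estimators are correct under the stated
model, not that they are robust to every artifact of real imaging.

## Numerical choices and degenerate inputs

- Constant (zero-variance) rest traces have no defined correlation; they
  are flagged and excluded from clustering. Degenerate residual columns
  are likewise excluded from the eigendecomposition and re-entered as
  zero rows in the eigenvectors.
- Empty occupancy bins are flagged `NA` in tuning curves and skipped by
  the information sum; for the wavelet transform they are linearly
  interpolated (circularly), since the CWT needs a complete curve.
- The shuffle test excludes rotations shorter than 1 s in either
  direction, keeping the null conservative for slowly varying traces.
- Event and ripple detectors return empty tables on flat inputs; the
  strength event detector requires at least one minute of data for its
  mean/SD to be meaningful.
- Ties in the Hopfield local field keep the current bit; the asynchronous
  fixed-order schedule avoids the 2-cycles possible under synchronous
  updates.
- All stochastic stages (shuffles, surrogate nulls, bootstraps, the
  generator) take explicit seeds; a fixed seed makes a session and every
  downstream deterministic stage bit-reproducible.

## Problem sizes used in the tests

The test suite validates recovery at deliberately modest scales: 40–60
neurons, 2.5–10 min rest blocks (20 min for the ensemble-recovery check),
300-shuffle nulls, 100-seed noise screens for the Marčenko–Pastur bound,
and 50-seed direction checks for explained variance. These sizes keep the
full suite to a few minutes while leaving each check statistically
meaningful; all of them are ordinary parameters, so any user can rerun
the same checks at full experimental scale.

## Known limitations

- The pipeline assumes deconvolved, non-negative event rates; raw ΔF/F
  would violate the sparsity assumptions of the ICA contrast.
- Ensemble membership is hard (disjoint sets); neurons shared between
  functional groups are assigned to one cluster by the dendrogram cut.
- The cue/trajectory dichotomy is a simplification — the encoding-bias
  ratio exposes the underlying continuum, and the labels should be read
  as tendencies rather than types.
- The Marčenko–Pastur bound is asymptotic; at small N the largest noise
  eigenvalue fluctuates around $\lambda_+$ and occasionally crosses it,
  so a handful of spurious residual components per hundred sessions is
  expected and harmless (they only enter the ICA basis, not the ensemble
  count).
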