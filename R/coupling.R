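# Temporal coordination between reactivations and SWRs: peri-event
# averages, cross-correlation lag estimation with a Gaussian peak fit,
# onset cross-correlograms, coupled cue-trajectory pair identification,
# feature similarity, SWR-association fractions, explained variance, and
# ensemble-persistence statistics.

#' Peri-event average of a time series
#'
#' Z-scores the series over the block and averages windows aligned to the
#' reference event times. Events whose window would cross the block edges
#' are dropped.
#'
#' @param series Numeric series (e.g. one ensemble's reactivation
#'   strength).
#' @param event_times_s Reference event times in seconds.
#' @param frame_rate_hz Sampling rate of `series`.
#' @param window_s Half-width of the window in seconds.
#' @return List of class `"peri_event_average"` with `lags_s`, `mean_z`,
#'   `sem` and `n_events`.
#' @export
peri_event_average <- function(series, event_times_s, frame_rate_hz = 19,
                               window_s = 1) {
  stopifnot(length(event_times_s) >= 1)
  z <- as.numeric(scale(series))
  half <- round(window_s * frame_rate_hz)
  centers <- round(event_times_s * frame_rate_hz) + 1L
  ok <- centers - half >= 1 & centers + half <= length(z)
  if (!any(ok)) stop("no events with a full window inside the block")
  centers <- centers[ok]
  Wm <- vapply(centers, function(c0) z[(c0 - half):(c0 + half)],
               numeric(2 * half + 1))
  Wm <- matrix(Wm, nrow = 2 * half + 1)
  structure(list(
    lags_s = seq(-half, half) / frame_rate_hz,
    mean_z = rowMeans(Wm),
    sem = apply(Wm, 1, stats::sd) / sqrt(ncol(Wm)),
    n_events = ncol(Wm)
  ), class = "peri_event_average")
}

# Unbiased-normalized cross-correlation of two equal-length series over
# integer lags -max_lag..max_lag. Positive lag means `b` follows `a`.
xcorr_unbiased <- function(a, b, max_lag) {
  Tn <- length(a)
  stopifnot(length(b) == Tn, max_lag < Tn)
  a <- a - mean(a); b <- b - mean(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      sum(a[seq_len(Tn - k)] * b[seq_len(Tn - k) + k]) / (Tn - k)
    } else {
      sum(b[seq_len(Tn + k)] * a[seq_len(Tn + k) - k]) / (Tn + k)
    }
  }, numeric(1))
  list(lags = lags, cc = cc / (sa * sb))
}

#' Cross-correlation lag with Gaussian peak fit
#'
#' Computes the unbiased-normalized cross-correlation between two series
#' over `+/- max_lag_s` and fits a Gaussian (amplitude, mean, width,
#' offset) to the coefficient curve; the fitted mean is the lag estimate.
#' A positive lag means the second series follows the first. If the fit
#' fails the argmax lag is returned with `fit_ok = FALSE`.
#'
#' @param a,b Equal-length series.
#' @param frame_rate_hz Sampling rate.
#' @param max_lag_s Maximum lag scanned.
#' @param dwell_ms Scanner dwell time per frame for the reported timing
#'   bound (see [scan_dwell_bound_ms()]).
#' @return List of class `"lag_estimate"`: `lag_s`, `coeff_peak`,
#'   `ci_halfwidth_s`, `fit_ok`, plus the raw `lags_s`/`cc` curve.
#' @export
xcorr_gaussian_lag <- function(a, b, frame_rate_hz = 19, max_lag_s = 1,
                               dwell_ms = 50) {
  max_lag <- round(max_lag_s * frame_rate_hz)
  xc <- xcorr_unbiased(a, b, max_lag)
  lag_s <- xc$lags / frame_rate_hz
  cc <- xc$cc
  i0 <- which.max(cc)
  start <- list(A = max(cc) - min(cc), mu = lag_s[i0],
                sig = max_lag_s / 4, off = min(cc))
  df <- data.frame(x = lag_s, y = cc)
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sig^2)) + off,
    data = df, start = start,
    lower = c(A = 0, mu = -max_lag_s, sig = 1e-3, off = -Inf),
    upper = c(A = Inf, mu = max_lag_s, sig = Inf, off = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    lag <- lag_s[i0]; ok <- FALSE
  } else {
    lag <- stats::coef(fit)[["mu"]]; ok <- TRUE
  }
  ci <- (dwell_ms / 3) / 1000 + 1 / frame_rate_hz
  structure(list(lag_s = lag, coeff_peak = cc[i0], ci_halfwidth_s = ci,
                 fit_ok = ok, lags_s = lag_s, cc = cc),
            class = "lag_estimate")
}

#' Cross-correlogram between two event-onset trains
#'
#' Histogram of all pairwise lags `a - b` within the window, with a
#' bootstrap confidence band obtained by resampling both event sets with
#' replacement.
#'
#' @param onsets_a,onsets_b Event onset times in seconds (>= 5 each).
#' @param bin_ms Histogram bin width.
#' @param window_s Half-width of the lag window.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed.
#' @return List of class `"onset_crosscorrelogram"` with `lag_centers_s`,
#'   `counts`, `ci_lower`, `ci_upper`.
#' @export
onset_crosscorrelogram <- function(onsets_a, onsets_b, bin_ms = 100,
                                   window_s = 1, n_boot = 500, seed = 1L) {
  stopifnot(length(onsets_a) >= 5, length(onsets_b) >= 5)
  breaks <- seq(-window_s, window_s, by = bin_ms / 1000)
  if (breaks[length(breaks)] < window_s) breaks <- c(breaks, window_s)
  count_fun <- function(a, b) {
    d <- as.vector(outer(a, b, "-"))
    d <- d[d >= -window_s & d <= window_s]
    graphics::hist(d, breaks = breaks, plot = FALSE)$counts
  }
  obs <- count_fun(onsets_a, onsets_b)
  set.seed(seed)
  boot <- replicate(n_boot, {
    count_fun(sample(onsets_a, replace = TRUE),
              sample(onsets_b, replace = TRUE))
  })
  structure(list(
    lag_centers_s = (breaks[-1] + breaks[-length(breaks)]) / 2,
    counts = obs,
    ci_lower = apply(boot, 1, stats::quantile, 0.025),
    ci_upper = apply(boot, 1, stats::quantile, 0.975)
  ), class = "onset_crosscorrelogram")
}

#' Identify temporally coupled cue-trajectory ensemble pairs
#'
#' For every (cue, trajectory) pair of strength series from one block, a
#' pair is coupled when the peak absolute cross-correlation within
#' `+/- window_s` exceeds the one-tailed `1 - alpha` bound of a
#' circular-shift surrogate null (the trajectory series is circularly
#' shifted by at least `min_shift_s`). The reported lag is the mean lag
#' weighted by the positive part of the correlation curve; positive lag
#' means the trajectory reactivation follows the cue reactivation.
#'
#' @param strengths_cue Frames x n_cue strength matrix (cue ensembles).
#' @param strengths_traj Frames x n_traj strength matrix.
#' @param frame_rate_hz Sampling rate.
#' @param window_s Lag window half-width (default 1 s).
#' @param alpha One-tailed significance level.
#' @param n_null Surrogate shifts per pair.
#' @param min_shift_s Minimum circular shift.
#' @param features_cue,features_traj Optional `"reactivated_features"`
#'   matrices; when given, each pair also gets the Pearson similarity of
#'   its features.
#' @param seed RNG seed.
#' @return Data frame of class `"coupled_pairs"`: `cue_id`, `traj_id`,
#'   `peak_cc`, `null_bound`, `coupled`, `lag_s`, and (optionally)
#'   `feature_r`, `feature_z`.
#' @export
find_coupled_pairs <- function(strengths_cue, strengths_traj,
                               frame_rate_hz = 19, window_s = 1,
                               alpha = 0.05, n_null = 500, min_shift_s = 1,
                               features_cue = NULL, features_traj = NULL,
                               seed = 1L) {
  strengths_cue <- as.matrix(strengths_cue)
  strengths_traj <- as.matrix(strengths_traj)
  Tn <- nrow(strengths_cue)
  stopifnot(nrow(strengths_traj) == Tn)
  max_lag <- round(window_s * frame_rate_hz)
  if (Tn <= 4 * max_lag) stop("series too short for the lag window")
  set.seed(seed)
  min_shift <- round(min_shift_s * frame_rate_hz)
  out <- NULL
  for (i in seq_len(ncol(strengths_cue))) {
    for (j in seq_len(ncol(strengths_traj))) {
      a <- strengths_cue[, i]; b <- strengths_traj[, j]
      xc <- xcorr_unbiased(a, b, max_lag)
      peak <- max(abs(xc$cc))
      shifts <- sample.int(Tn - 2L * min_shift, n_null, replace = TRUE) + min_shift
      null_peaks <- vapply(shifts, function(s) {
        bs <- b[((seq_len(Tn) - 1L + s) %% Tn) + 1L]
        max(abs(xcorr_unbiased(a, bs, max_lag)$cc))
      }, numeric(1))
      bound <- stats::quantile(null_peaks, 1 - alpha, names = FALSE)
      wts <- pmax(xc$cc, 0)
      lag <- if (sum(wts) > 0) sum(wts * xc$lags) / sum(wts) / frame_rate_hz
             else NA_real_
      row <- data.frame(cue_id = i, traj_id = j, peak_cc = peak,
                        null_bound = bound, coupled = peak > bound,
                        lag_s = lag)
      if (!is.null(features_cue) && !is.null(features_traj)) {
        fs <- feature_similarity(features_cue[i, ], features_traj[j, ])
        row$feature_r <- fs$r
        row$feature_z <- fs$z
      }
      out <- rbind(out, row)
    }
  }
  class(out) <- c("coupled_pairs", "data.frame")
  out
}

#' Pearson similarity between two reactivated features
#'
#' @param f_cue,f_traj Feature vectors over the same spatial bins.
#' @return List with `r` and the Fisher transform `z = atanh(r)`; both `NA`
#'   when either feature has zero variance.
#' @export
feature_similarity <- function(f_cue, f_traj) {
  stopifnot(length(f_cue) == length(f_traj))
  if (stats::sd(f_cue) == 0 || stats::sd(f_traj) == 0) {
    return(list(r = NA_real_, z = NA_real_, degenerate = TRUE))
  }
  r <- stats::cor(f_cue, f_traj)
  list(r = r, z = atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)),
       degenerate = FALSE)
}

#' Fraction of reactivation events associated with an SWR
#'
#' @param event_onsets_s Reactivation event onsets (s).
#' @param swr_onsets_s SWR onsets on the same clock.
#' @param window_s Association half-window (default 0.5 s).
#' @return Percentage of reactivation events whose onset falls within
#'   `+/- window_s` of any SWR onset.
#' @export
swr_association_fraction <- function(event_onsets_s, swr_onsets_s,
                                     window_s = 0.5) {
  if (length(event_onsets_s) == 0) return(NA_real_)
  if (length(swr_onsets_s) == 0) return(0)
  hit <- vapply(event_onsets_s, function(t)
    any(abs(t - swr_onsets_s) <= window_s), logical(1))
  100 * mean(hit)
}

#' Explained variance and reverse explained variance
#'
#' Measures how much of the RUN pairwise-correlation structure reappears in
#' REST2 beyond what was already present in REST1: the squared partial
#' correlation of the (RUN, REST2) pair-correlation vectors controlling for
#' REST1, as a percentage. `rev` swaps the two rest epochs and serves as
#' the control.
#'
#' @param X_rest1,X_run,X_rest2 Frames x neurons activity matrices with the
#'   same neurons (>= 5).
#' @param mask_rest1,mask_rest2 Optional movement masks for the rest
#'   blocks.
#' @return List with `ev_percent` and `rev_percent`.
#' @export
explained_variance <- function(X_rest1, X_run, X_rest2,
                               mask_rest1 = NULL, mask_rest2 = NULL) {
  stopifnot(ncol(X_rest1) == ncol(X_run), ncol(X_run) == ncol(X_rest2))
  if (ncol(X_run) < 5) stop("need at least 5 neurons for explained variance")
  X1 <- if (is.null(mask_rest1)) X_rest1 else X_rest1[!mask_rest1, , drop = FALSE]
  X2 <- if (is.null(mask_rest2)) X_rest2 else X_rest2[!mask_rest2, , drop = FALSE]
  ok <- apply(X1, 2, stats::sd) > 0 & apply(X_run, 2, stats::sd) > 0 &
    apply(X2, 2, stats::sd) > 0
  if (sum(ok) < 5) stop("fewer than 5 neurons with variance in all blocks")
  pair_cor <- function(X) {
    r <- stats::cor(X[, ok, drop = FALSE])
    r[upper.tri(r)]
  }
  r1 <- pair_cor(X1)
  rr <- pair_cor(X_run)
  r2 <- pair_cor(X2)
  partial2 <- function(ab, ac, bc) {
    ((ab - ac * bc) / sqrt((1 - ac^2) * (1 - bc^2)))^2
  }
  r_run_r2 <- stats::cor(rr, r2)
  r_run_r1 <- stats::cor(rr, r1)
  r_r1_r2 <- stats::cor(r1, r2)
  list(ev_percent = 100 * partial2(r_run_r2, r_run_r1, r_r1_r2),
       rev_percent = 100 * partial2(r_run_r1, r_run_r2, r_r1_r2))
}

#' Jaccard overlap between two ensembles' member sets
#'
#' `J = O / (A + B - O)` for `O` overlapping members out of `A` and `B`.
#'
#' @param members_a,members_b Member index vectors.
#' @return The Jaccard index in `[0, 1]`.
#' @export
jaccard_persistence <- function(members_a, members_b) {
  A <- length(unique(members_a)); B <- length(unique(members_b))
  if (A + B == 0) stop("Jaccard index undefined for two empty sets")
  O <- length(intersect(members_a, members_b))
  O / (A + B - O)
}

#' Maximum Jaccard persistence of an ensemble against a set
#'
#' For comparing one REST2 ensemble against all REST1 ensembles: the
#' maximum pairwise Jaccard index.
#'
#' @param members Member indices of the reference ensemble.
#' @param member_sets List of member index vectors to compare against.
#' @return Maximum Jaccard index (0 when `member_sets` is empty).
#' @export
max_jaccard <- function(members, member_sets) {
  member_sets <- ensemble_members(member_sets)
  if (length(member_sets) == 0) return(0)
  max(vapply(member_sets, jaccard_persistence, numeric(1),
             members_a = members))
}

#' Significance of ensemble overlap by Fisher's exact test
#'
#' One-tailed Fisher test on the 2x2 membership table against the null
#' that the overlap is no higher than chance; the ensemble pair is
#' persistent when `p < alpha` (0.001 by default).
#'
#' @param O Overlapping members.
#' @param A,B Sizes of the two ensembles.
#' @param n_total Total neurons in the session.
#' @param alpha Significance level.
#' @return List with `p_value` and `persistent`.
#' @export
persistence_significance <- function(O, A, B, n_total, alpha = 0.001) {
  stopifnot(O >= 0, O <= min(A, B), A <= n_total, B <= n_total,
            A + B - O <= n_total)
  tab <- matrix(c(O, A - O, B - O, n_total - A - B + O), 2, 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(p_value = p, persistent = p < alpha)
}
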