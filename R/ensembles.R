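# Resting-state ensembles: agglomerative clustering of smoothed, z-scored
# rest traces at the d = 1 - r distance, trajectory-segment extraction from
# member tuning curves, and cue/trajectory classification.

#' Pairwise correlation distance between rest traces
#'
#' Traces are Gaussian smoothed (sigma = 200 ms by default) to absorb
#' temporal jitter, movement frames are removed, the traces are z-scored,
#' and the Pearson correlation r between every pair is converted to the
#' distance `d = 1 - r` (0 = identical, 1 = unrelated, 2 = anti-correlated).
#' Constant traces have no defined correlation; they are flagged and
#' excluded from clustering.
#'
#' @param rest_activity Frames x neurons rest activity matrix.
#' @param movement_mask Logical per-frame flag of movement epochs to drop.
#' @param sigma_ms Smoothing kernel SD in ms.
#' @param frame_rate_hz Imaging frame rate.
#' @return Object of class `"distance_matrix"`: the full `d` matrix (NA
#'   rows/cols for degenerate neurons) and the logical `valid` vector.
#' @export
correlation_distance <- function(rest_activity, movement_mask = NULL,
                                 sigma_ms = 200, frame_rate_hz = 19) {
  stopifnot(is.matrix(rest_activity), ncol(rest_activity) >= 2)
  X <- rest_activity
  if (!is.null(movement_mask)) {
    stopifnot(length(movement_mask) == nrow(X))
    X <- X[!movement_mask, , drop = FALSE]
  }
  sigma <- sigma_ms / 1000 * frame_rate_hz
  X <- gauss_smooth(X, sigma)
  sds <- apply(X, 2, stats::sd)
  valid <- is.finite(sds) & sds > 0
  d <- matrix(NA_real_, ncol(X), ncol(X))
  if (sum(valid) >= 2) {
    r <- stats::cor(X[, valid, drop = FALSE])
    d[valid, valid] <- cor_to_dist(r)
  }
  diag(d) <- 0
  structure(list(d = d, valid = valid, n_frames = nrow(X)),
            class = "distance_matrix")
}

#' Detect synchronous ensembles by agglomerative clustering
#'
#' Average-linkage (UPGMA) hierarchical clustering on the correlation
#' distance, with the dendrogram cut at `cutoff` (0.75, i.e. an average
#' within-cluster correlation of 0.25). Clusters with fewer than `min_size`
#' members are not ensembles.
#'
#' @param dm A [correlation_distance()] result.
#' @param cutoff Dendrogram cut height (distance units).
#' @param min_size Minimum ensemble membership (default 5).
#' @param block Label stored on each ensemble (`"rest1"`/`"rest2"`).
#' @return Object of class `"ensemble_set"`: a list of ensembles, each with
#'   `members` (neuron indices), `label` (`NA` until classified), and
#'   `block`. Ensembles are ordered by decreasing size.
#' @export
detect_ensembles <- function(dm, cutoff = 0.75, min_size = 5, block = "rest2") {
  stopifnot(inherits(dm, "distance_matrix"))
  ids <- which(dm$valid)
  out <- list()
  if (length(ids) >= min_size) {
    d <- stats::as.dist(dm$d[ids, ids])
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = cutoff)
    tab <- table(cl)
    keep <- as.integer(names(tab)[tab >= min_size])
    keep <- keep[order(-tab[as.character(keep)])]
    for (k in keep) {
      out[[length(out) + 1L]] <- list(members = sort(ids[cl == k]),
                                      label = NA_character_,
                                      segments = NULL, block = block)
    }
  }
  structure(list(ensembles = out, cutoff = cutoff, min_size = min_size,
                 block = block), class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("%d ensemble(s) in %s (cutoff %.2f, min size %d)\n",
              length(x$ensembles), x$block, x$cutoff, x$min_size))
  for (i in seq_along(x$ensembles)) {
    e <- x$ensembles[[i]]
    cat(sprintf("  #%d: %d members%s\n", i, length(e$members),
                if (is.na(e$label)) "" else paste0(", ", e$label)))
  }
  invisible(x)
}

#' @export
length.ensemble_set <- function(x) length(x$ensembles)

# Member index sets of an ensemble_set (or pass-through for a plain list).
ensemble_members <- function(x) {
  if (inherits(x, "ensemble_set")) lapply(x$ensembles, `[[`, "members") else x
}

#' Extract the trajectory segments encoded by an ensemble
#'
#' Each spatially-selective member's trial-averaged tuning curve is min-max
#' normalized to `[0, 1]`; the segments are the contiguous (circularly
#' wrapped) stretches of the belt where any member's normalized tuning
#' exceeds 0.5. Segments supported by fewer than 3 spatially-selective
#' cells are discarded, and ensembles with fewer than 3 spatially-selective
#' members yield no segments at all.
#'
#' @param members Neuron indices of the ensemble.
#' @param spatial A [classify_spatial_cells()] result for the RUN block.
#' @param threshold Normalized-activity threshold (default 0.5).
#' @return Data frame of segments: `start_cm`, `end_cm`, `length_cm`,
#'   `wrapped`, `n_cells`.
#' @export
extract_trajectory_segments <- function(members, spatial, threshold = 0.5) {
  stopifnot(inherits(spatial, "spatial_cell_results"))
  n_bins <- spatial$n_bins
  L <- spatial$belt_length_cm
  binw <- L / n_bins
  empty <- data.frame(start_cm = numeric(), end_cm = numeric(),
                      length_cm = numeric(), wrapped = logical(),
                      n_cells = integer())
  sp_members <- members[spatial$summary$is_spatial[members]]
  if (length(sp_members) < 3) return(empty)

  supra <- matrix(FALSE, length(sp_members), n_bins)
  for (k in seq_along(sp_members)) {
    v <- spatial$tuning[sp_members[k], ]
    v[is.na(v)] <- 0
    rng <- range(v)
    if (diff(rng) <= 0) next
    supra[k, ] <- (v - rng[1]) / diff(rng) > threshold
  }
  union_flag <- colSums(supra) > 0
  runs <- logical_runs(union_flag, circular = TRUE)
  if (nrow(runs) == 0) return(empty)

  out <- empty
  for (i in seq_len(nrow(runs))) {
    idx <- run_indices(runs$start[i], runs$end[i], n_bins)
    n_cells <- sum(apply(supra[, idx, drop = FALSE], 1, any))
    if (n_cells < 3) next
    out <- rbind(out, data.frame(
      start_cm = (runs$start[i] - 1) * binw,
      end_cm = runs$end[i] * binw,
      length_cm = length(idx) * binw,
      wrapped = runs$wrapped[i],
      n_cells = n_cells
    ))
  }
  out
}

#' Classify an ensemble as cue, trajectory, or unclassified
#'
#' An ensemble carrying a segment shorter than `cue_max_len_cm` (30 cm)
#' that spans the centre of a cue is a cue ensemble; otherwise any
#' remaining segment makes it a trajectory ensemble; with no segments it
#' stays unclassified (`"none"`). When both a qualifying cue segment and
#' longer segments exist, cue wins.
#'
#' @param segments Segment table from [extract_trajectory_segments()].
#' @param cue_centers_cm Cue centre positions.
#' @param belt_length_cm Belt length (for circular containment).
#' @param cue_max_len_cm Maximum length of a cue segment.
#' @return `"cue"`, `"trajectory"` or `"none"`.
#' @export
classify_ensemble <- function(segments, cue_centers_cm, belt_length_cm = 150,
                              cue_max_len_cm = 30) {
  if (is.null(segments) || nrow(segments) == 0) return("none")
  contains <- function(s, e, wrapped, x) {
    if (!wrapped) x >= s & x <= e else x >= s | x <= e
  }
  for (i in seq_len(nrow(segments))) {
    if (segments$length_cm[i] < cue_max_len_cm &&
        any(contains(segments$start_cm[i], segments$end_cm[i],
                     segments$wrapped[i], cue_centers_cm))) {
      return("cue")
    }
  }
  "trajectory"
}

#' Classify all ensembles of a set
#'
#' Convenience wrapper composing [extract_trajectory_segments()] and
#' [classify_ensemble()] over an [detect_ensembles()] result.
#'
#' @param es An `"ensemble_set"`.
#' @param spatial A [classify_spatial_cells()] result.
#' @param cue_centers_cm Cue centre positions.
#' @return The set with `label` and `segments` filled in per ensemble.
#' @export
classify_ensembles <- function(es, spatial, cue_centers_cm) {
  stopifnot(inherits(es, "ensemble_set"))
  for (i in seq_along(es$ensembles)) {
    seg <- extract_trajectory_segments(es$ensembles[[i]]$members, spatial)
    es$ensembles[[i]]$segments <- seg
    es$ensembles[[i]]$label <- classify_ensemble(
      seg, cue_centers_cm, spatial$belt_length_cm)
  }
  es
}

#' Cue-versus-place encoding bias of one neuron
#'
#' Fits two models of the binned RUN activity under a Poisson observation
#' model: (i) a Gaussian spatial tuning curve (baseline, amplitude, centre,
#' width; circular distance), a first-order place-cell approximation, and
#' (ii) a distinct rate at each cue location plus a constant baseline, a
#' stimulus-driven response. Both are fitted by maximum likelihood (the cue
#' model in closed form; the Gaussian model by bounded optimization with a
#' multi-start over the centre). The returned ratio `ll_cue - ll_place` is
#' positive for cue-like and negative for place-like neurons.
#'
#' @param activity Per-frame activity of the neuron.
#' @param position_cm Per-frame position.
#' @param cue_centers_cm,cue_width_cm Cue layout.
#' @param belt_length_cm,n_bins Spatial binning.
#' @return Object of class `"encoding_bias"` with `ll_place`, `ll_cue`,
#'   `ratio`, and the fitted Gaussian parameters.
#' @export
encoding_bias <- function(activity, position_cm, cue_centers_cm,
                          cue_width_cm = 9, belt_length_cm = 150, n_bins = 50) {
  stopifnot(length(activity) == length(position_cm))
  if (max(lap_index(position_cm, belt_length_cm)) < 10) {
    stop("at least 10 laps are required to fit encoding models")
  }
  if (all(activity == 0)) stop("silent neuron: encoding bias undefined")
  bins <- pmin(floor(position_cm / belt_length_cm * n_bins) + 1L, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  y <- rep(0, n_bins)
  occ <- counts > 0
  y[occ] <- as.numeric(rowsum(activity, factor(bins, levels = which(occ))))
  ctr <- (seq_len(n_bins) - 0.5) * belt_length_cm / n_bins
  eps <- 1e-8

  pois_ll <- function(rate) {
    rate <- pmax(rate, eps)
    sum(y[occ] * log(rate[occ]) - counts[occ] * rate[occ])
  }

  # Gaussian-tuning model
  nll_gauss <- function(par) {
    rate <- par[1] + par[2] *
      exp(-circ_dist(ctr, par[3], belt_length_cm)^2 / (2 * par[4]^2))
    -pois_ll(rate)
  }
  mean_rate <- sum(y) / sum(counts)
  best <- NULL
  for (c0 in seq(belt_length_cm / 20, belt_length_cm, by = belt_length_cm / 10)) {
    fit <- try(stats::optim(
      c(b = max(mean_rate / 2, eps), a = max(mean_rate, eps), c = c0, w = 8),
      nll_gauss, method = "L-BFGS-B",
      lower = c(0, 0, 0, 1.5),
      upper = c(Inf, Inf, belt_length_cm, belt_length_cm / 2)), silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Gaussian tuning fit failed")
  ll_place <- -best$value

  # cue model: closed-form MLE rates in cue windows and baseline
  in_cue <- matrix(FALSE, n_bins, length(cue_centers_cm))
  for (j in seq_along(cue_centers_cm)) {
    in_cue[, j] <- circ_dist(ctr, cue_centers_cm[j], belt_length_cm) <=
      cue_width_cm / 2
  }
  region <- apply(in_cue, 1, function(r) if (any(r)) which(r)[1] else 0L)
  ll_cue <- 0
  for (g in sort(unique(region))) {
    sel <- occ & region == g
    if (!any(sel)) next
    rate <- max(sum(y[sel]) / sum(counts[sel]), eps)
    ll_cue <- ll_cue + sum(y[sel] * log(rate) - counts[sel] * rate)
  }

  structure(list(ll_place = ll_place, ll_cue = ll_cue,
                 ratio = ll_cue - ll_place,
                 gauss_par = best$par), class = "encoding_bias")
}

#' @export
print.encoding_bias <- function(x, ...) {
  cat(sprintf("Encoding bias (cue - place log-likelihood): %.2f (%s-leaning)\n",
              x$ratio, if (x$ratio > 0) "cue" else "place"))
  invisible(x)
}

#' Hypergeometric enrichment of spatial cells in an ensemble
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` spatially
#' selective members in an ensemble of size `m`, when `K` of the `N`
#' recorded neurons are spatially selective.
#'
#' @param k Spatially-selective members observed in the ensemble.
#' @param m Ensemble size.
#' @param K Total spatially-selective neurons in the session.
#' @param N Total neurons recorded.
#' @return The enrichment p-value.
#' @export
hypergeometric_enrichment <- function(k, m, K, N) {
  stopifnot(k >= 0, m >= 1, K >= 0, N >= 1, m <= N, K <= N, k <= min(m, K))
  stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}
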