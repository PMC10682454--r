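# Shared numeric helpers used across the pipeline stages.

#' Convert a Pearson correlation into the clustering distance
#'
#' The ensemble detector works on the distance `d = 1 - r`, so perfectly
#' correlated traces sit at distance 0, unrelated traces at 1 and perfectly
#' anti-correlated traces at 2. The dendrogram cut-off of 0.75 used by
#' [detect_ensembles()] therefore corresponds to an average within-cluster
#' correlation of 0.25.
#'
#' @param r Pearson correlation coefficient(s) in `[-1, 1]`.
#' @return Distance value(s) in `[0, 2]`.
#' @export
#' @examples
#' cor_to_dist(0.25)  # the default dendrogram cut-off
cor_to_dist <- function(r) {
  stopifnot(is.numeric(r), all(is.na(r) | (r >= -1 & r <= 1)))
  1 - r
}

#' Express a trajectory-segment length as a percentage of the belt
#'
#' @param length_cm Segment length(s) in cm.
#' @param belt_length_cm Total belt length in cm (default 150).
#' @return Percentage of the belt covered by the segment.
#' @export
#' @examples
#' segment_length_pct(36)  # 24% of a 150 cm belt
segment_length_pct <- function(length_cm, belt_length_cm = 150) {
  stopifnot(belt_length_cm > 0, all(length_cm >= 0))
  100 * length_cm / belt_length_cm
}

#' Scan dwell-time bound on imaging-derived lag estimates
#'
#' Resonant-galvo frame scanning spends the frame's dwell time sweeping the
#' field of view, so two neurons in the same frame are sampled up to one
#' dwell apart; averaged over random positions the expected offset between
#' two neurons is a third of the dwell time. Lags measured from imaging
#' traces therefore carry this irreducible +/- bound.
#'
#' @param dwell_ms Per-frame dwell time of the scanner in ms (default 50).
#' @return Half-width of the timing bound in ms.
#' @export
#' @examples
#' scan_dwell_bound_ms()  # ~16.7 ms for a 50 ms dwell
scan_dwell_bound_ms <- function(dwell_ms = 50) {
  stopifnot(dwell_ms >= 0)
  dwell_ms / 3
}

# Circular distance between positions on a belt of length L.
circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

# Gaussian smoothing of the columns of a matrix (or a vector), sigma in
# frames. Kernel truncated at 4 sigma; edges renormalized so flat inputs
# stay flat.
gauss_smooth <- function(x, sigma) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  if (sigma <= 0) return(if (vec) as.numeric(X) else X)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  Tn <- nrow(X)
  out <- apply(X, 2, function(col) {
    num <- stats::convolve(col, rev(k), type = "open")
    den <- stats::convolve(rep(1, Tn), rev(k), type = "open")
    (num / den)[(half + 1):(half + Tn)]
  })
  if (vec) as.numeric(out) else out
}

# Column z-scoring against supplied (or own) statistics. Zero-SD columns are
# mapped to 0 and reported via the "degenerate" attribute.
standardize_columns <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, stats::sd)
  degenerate <- !is.finite(scale) | scale <= 0
  scl <- ifelse(degenerate, 1, scale)
  Z <- sweep(sweep(X, 2, center, "-"), 2, scl, "/")
  Z[, degenerate] <- 0
  attr(Z, "center") <- center
  attr(Z, "scale") <- scale
  attr(Z, "degenerate") <- degenerate
  Z
}

# Contiguous runs of TRUE in a logical vector; optionally treating the
# vector as circular (a run wrapping the end joins the first run).
logical_runs <- function(flag, circular = FALSE) {
  n <- length(flag)
  if (n == 0 || !any(flag)) {
    return(data.frame(start = integer(), end = integer(), wrapped = logical()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     wrapped = FALSE)
  if (circular && nrow(runs) > 1 && runs$start[1] == 1L && runs$end[nrow(runs)] == n) {
    runs$start[1] <- runs$start[nrow(runs)]
    runs$wrapped[1] <- TRUE
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  runs
}

# Expand a (possibly wrapped) run into its member indices on a circle of n.
run_indices <- function(start, end, n) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, n), seq.int(1L, end))
}

# Lap index per RUN frame: increments every time the position wraps back
# past the start/reward line.
lap_index <- function(position_cm, belt_length_cm) {
  wraps <- c(FALSE, diff(position_cm) < -belt_length_cm / 2)
  cumsum(wraps) + 1L
}
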