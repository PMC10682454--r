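# Spatial tuning: tuning curves over 50 belt bins, spatial information with
# a circular-shuffle null, and place-field detection by a Ricker-wavelet
# continuous wavelet transform on the (circular) tuning curve.

#' Compute a spatial tuning curve
#'
#' Bins the belt into `n_bins` half-open bins `[b*L/N, (b+1)*L/N)` and takes
#' the occupancy-weighted mean activity per bin. Bins the animal never
#' visited are flagged (`NA` values) and excluded from the spatial
#' information sum.
#'
#' @param activity Per-frame deconvolved activity of one neuron.
#' @param position_cm Per-frame position on the belt.
#' @param n_bins Number of spatial bins (default 50).
#' @param belt_length_cm Belt length in cm (default 150).
#' @return An object of class `"tuning_curve"` with `values` (mean activity
#'   per bin, `NA` where unoccupied), `occupancy` (fraction of frames per
#'   bin, sums to 1), and `overall_mean`.
#' @export
compute_tuning_curve <- function(activity, position_cm, n_bins = 50,
                                 belt_length_cm = 150) {
  stopifnot(length(activity) == length(position_cm), length(activity) > 0,
            all(position_cm >= 0), all(position_cm < belt_length_cm))
  bins <- pmin(floor(position_cm / belt_length_cm * n_bins) + 1L, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  # rowsum drops empty groups; rebuild on the full bin grid
  grp <- sort(unique(bins))
  full <- rep(NA_real_, n_bins)
  full[grp] <- as.numeric(rowsum(activity, factor(bins, levels = grp)))
  values <- ifelse(counts > 0, full / pmax(counts, 1), NA_real_)
  structure(list(
    values = values,
    occupancy = counts / length(activity),
    overall_mean = mean(activity),
    n_bins = n_bins,
    belt_length_cm = belt_length_cm
  ), class = "tuning_curve")
}

#' Spatial information of a tuning curve (bits)
#'
#' `I = sum_i p_i * (f_i / f) * log2(f_i / f)` over occupied bins, where
#' `f_i` is the mean activity in bin i, `p_i` the occupancy fraction and `f`
#' the overall mean. Bins with `f_i = 0` contribute nothing.
#'
#' @param tc A [compute_tuning_curve()] result.
#' @return Spatial information in bits (non-negative).
#' @export
spatial_information <- function(tc) {
  stopifnot(inherits(tc, "tuning_curve"))
  f <- tc$overall_mean
  if (!is.finite(f) || f <= 0) stop("overall mean activity must be positive")
  occ <- !is.na(tc$values)
  fi <- tc$values[occ]
  pi_ <- tc$occupancy[occ]
  pos <- fi > 0
  sum(pi_[pos] * (fi[pos] / f) * log2(fi[pos] / f))
}

# Spatial information for many activity columns sharing one position trace;
# rows of `A` are frames. Used by the shuffle test and the cell classifier.
si_matrix <- function(A, bins, n_bins) {
  counts <- tabulate(bins, nbins = n_bins)
  occ <- counts / nrow(A)
  grp <- factor(bins, levels = which(counts > 0))
  sums <- rowsum(A, grp)  # occupied bins x columns
  fi <- sums / counts[counts > 0]
  f <- colMeans(A)
  rel <- sweep(fi, 2, f, "/")
  terms <- occ[counts > 0] * rel * ifelse(rel > 0, log2(rel), 0)
  out <- colSums(terms)
  out[f <= 0] <- NA_real_
  out
}

#' Circular-shuffle significance test for spatial information
#'
#' The null distribution is built by circularly rotating the activity trace
#' by a random offset (at least `min_shift_s` away from zero in either
#' direction, keeping the null conservative) and recomputing the spatial
#' information. The p-value is the fraction of shuffles whose information
#' reaches the observed value; a neuron passes at `p < 0.05` (the 95th
#' percentile rule).
#'
#' @param activity,position_cm Per-frame traces.
#' @param n_shuffles Number of circular shuffles (>= 100).
#' @param seed RNG seed for the offsets.
#' @param frame_rate_hz Imaging frame rate, used for the minimum shift.
#' @param min_shift_s Minimum rotation in seconds (default 1).
#' @param n_bins,belt_length_cm Binning as in [compute_tuning_curve()].
#' @return List with `si_bits`, `p_value` and the shuffled values.
#' @export
shuffle_test <- function(activity, position_cm, n_shuffles = 1000, seed = 1L,
                         frame_rate_hz = 19, min_shift_s = 1,
                         n_bins = 50, belt_length_cm = 150) {
  stopifnot(n_shuffles >= 100, length(activity) == length(position_cm))
  Tn <- length(activity)
  if (all(activity == 0)) {
    return(list(si_bits = NA_real_, p_value = 1, null = rep(NA_real_, n_shuffles)))
  }
  bins <- pmin(floor(position_cm / belt_length_cm * n_bins) + 1L, n_bins)
  obs <- si_matrix(matrix(activity, ncol = 1), bins, n_bins)[1]
  set.seed(seed)
  min_off <- max(1L, round(min_shift_s * frame_rate_hz))
  if (2L * min_off >= Tn) min_off <- 1L
  offs <- sample.int(Tn - 2L * min_off, n_shuffles, replace = TRUE) + min_off
  idx <- outer(seq_len(Tn) - 1L, offs, function(t, o) ((t + o) %% Tn) + 1L)
  A <- matrix(activity[idx], Tn, n_shuffles)
  null <- si_matrix(A, bins, n_bins)
  p <- mean(null >= obs, na.rm = TRUE)
  list(si_bits = obs, p_value = p, null = null)
}

# Ricker (Mexican-hat) wavelet sampled on integer offsets for a given scale,
# normalized as in the standard CWT.
ricker_kernel <- function(scale, half_len) {
  x <- seq(-half_len, half_len)
  a <- scale
  A <- 2 / (sqrt(3 * a) * pi^0.25)
  A * (1 - (x / a)^2) * exp(-x^2 / (2 * a^2))
}

# CWT of a circular curve at integer scales: circular convolution with the
# Ricker kernel, one row per scale.
ricker_cwt <- function(values, scales) {
  n <- length(values)
  ext <- c(values, values, values)  # circular extension
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    k <- ricker_kernel(scales[si], n)  # support +/- n covers the wrap
    conv <- stats::convolve(ext, rev(k), type = "open")
    mid <- (length(k) - 1) / 2
    out[si, ] <- conv[(n + mid + 1):(2 * n + mid)]
  }
  out
}

#' Detect place fields by Ricker-wavelet transform of the tuning curve
#'
#' Runs a continuous wavelet transform (Ricker wavelet, scales 1..`n_bins`)
#' over the circularly extended tuning curve. Local coefficient maxima
#' exceeding 3 median absolute deviations above the median of the scale-1
#' coefficients are field candidates; overlapping candidates (one centre
#' inside the other's bounds) are resolved in favour of the dominant
#' wavelet response, so each field is reported once at its best-matched
#' scale. Surviving fields
#' must have a width (distance between the Ricker zero-crossings, i.e.
#' 2 x scale bins) between 5% and 80% of the belt, in-field mean activity
#' at least 2.5 x the out-of-field mean, and the per-lap activity peak
#' inside the field on at least a third of the laps.
#'
#' @param tc A [compute_tuning_curve()] result.
#' @param per_lap_activity Laps x bins matrix of mean activity per lap; at
#'   least 10 laps are required (sessions with fewer laps are excluded).
#' @param mad_mult Threshold multiplier on the scale-1 MAD (default 3).
#' @return A list of fields, each with `center_bin`, `width_bins`, `scale`
#'   and the member `bins` (circular).
#' @export
detect_place_fields <- function(tc, per_lap_activity, mad_mult = 3) {
  stopifnot(inherits(tc, "tuning_curve"))
  if (is.null(dim(per_lap_activity)) || nrow(per_lap_activity) < 10) {
    stop("at least 10 laps are required for place-field detection")
  }
  n <- tc$n_bins
  stopifnot(ncol(per_lap_activity) == n)
  v <- tc$values
  if (anyNA(v)) {  # interpolate over unoccupied bins (circular)
    occ <- which(!is.na(v))
    if (length(occ) == 0) return(list())
    v <- stats::approx(occ, v[occ], xout = seq_len(n), rule = 2)$y
  }
  if (all(v == v[1])) return(list())

  scales <- seq_len(n)
  W <- ricker_cwt(v, scales)
  c1 <- W[1, ]
  thr <- stats::median(c1) + mad_mult * stats::mad(c1, constant = 1)

  # candidate (scale, bin) local maxima along the bin axis (circular);
  # only scales whose field width (2 x scale) lies within the allowed
  # 5-80% of the track can host a potential field
  scales <- scales[2 * scales >= 0.05 * n & 2 * scales <= 0.80 * n]
  W <- W[scales, , drop = FALSE]
  cands <- list()
  for (si in seq_along(scales)) {
    row <- W[si, ]
    left <- row[c(n, seq_len(n - 1))]
    right <- row[c(2:n, 1)]
    peaks <- which(row > left & row >= right & row > thr)
    for (b in peaks) cands[[length(cands) + 1L]] <- c(scale = scales[si], bin = b)
  }
  if (length(cands) == 0) return(list())
  cand <- do.call(rbind, cands)
  coefs <- W[cbind(match(cand[, "scale"], scales), cand[, "bin"])]
  cand <- cand[order(-coefs), , drop = FALSE]

  # resolve nested responses: walk candidates from the dominant coefficient
  # down; a candidate is discarded when it overlaps an already-kept field
  # (its centre inside the kept bounds, or the kept centre inside its own
  # bounds), so one field keeps a single, best-matched scale
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    sc <- cand[i, "scale"]; b <- cand[i, "bin"]
    nested <- FALSE
    for (f in kept) {
      d <- min(abs(b - f$center_bin), n - abs(b - f$center_bin))
      if (d <= f$scale || d <= sc) { nested <- TRUE; break }
    }
    if (!nested) {
      kept[[length(kept) + 1L]] <- list(center_bin = b, scale = sc,
                                        width_bins = 2 * sc)
    }
  }

  # width constraint: 5% to 80% of the belt
  kept <- Filter(function(f) f$width_bins >= 0.05 * n && f$width_bins <= 0.80 * n,
                 kept)
  if (length(kept) == 0) return(list())
  for (i in seq_along(kept)) {
    f <- kept[[i]]
    half <- f$scale
    bins <- ((f$center_bin - half):(f$center_bin + half) - 1L) %% n + 1L
    kept[[i]]$bins <- sort(unique(bins))
  }

  # in-field mean >= 2.5 x out-of-field mean (out = outside every candidate)
  all_field_bins <- sort(unique(unlist(lapply(kept, `[[`, "bins"))))
  out_bins <- setdiff(seq_len(n), all_field_bins)
  out_mean <- if (length(out_bins) > 0) mean(v[out_bins]) else 0
  kept <- Filter(function(f) {
    inm <- mean(v[f$bins])
    inm > 0 && (out_mean <= 0 || inm >= 2.5 * out_mean)
  }, kept)
  if (length(kept) == 0) return(list())

  # lap consistency: per-lap peak inside the field on >= 1/3 of active laps
  lap_peak <- apply(per_lap_activity, 1, function(row) {
    if (all(!is.finite(row)) || max(row, na.rm = TRUE) <= 0) NA_integer_
    else which.max(row)
  })
  lap_peak <- lap_peak[!is.na(lap_peak)]
  kept <- Filter(function(f) {
    length(lap_peak) > 0 && mean(lap_peak %in% f$bins) >= 1 / 3
  }, kept)
  kept
}

# Laps x bins matrix of mean activity for one neuron.
per_lap_matrix <- function(activity, position_cm, n_bins, belt_length_cm) {
  laps <- lap_index(position_cm, belt_length_cm)
  bins <- pmin(floor(position_cm / belt_length_cm * n_bins) + 1L, n_bins)
  n_laps <- max(laps)
  M <- matrix(NA_real_, n_laps, n_bins)
  key <- (laps - 1L) * n_bins + bins
  sums <- rowsum(activity, key)
  cnts <- rowsum(rep(1, length(key)), key)
  kidx <- as.integer(rownames(sums))
  M[cbind((kidx - 1L) %/% n_bins + 1L, (kidx - 1L) %% n_bins + 1L)] <-
    sums / cnts
  M
}

#' Classify spatially-selective neurons in a RUN block
#'
#' A neuron is spatially selective when (i) its spatial information exceeds
#' the 95th percentile of the circular-shuffle null (`p < 0.05`) and (ii) it
#' supports at least one place field passing all field constraints.
#'
#' @param run_activity Frames x neurons RUN activity matrix.
#' @param position_cm Per-frame position.
#' @param n_bins,belt_length_cm Spatial binning.
#' @param n_shuffles Shuffles per neuron for the information null.
#' @param frame_rate_hz Frame rate (minimum shuffle offset of 1 s).
#' @param seed RNG seed.
#' @return An object of class `"spatial_cell_results"`: a list with a
#'   per-neuron data frame `summary` (si_bits, si_p, n_fields, is_spatial),
#'   per-neuron `fields`, and the `tuning` matrix (neurons x bins).
#' @export
classify_spatial_cells <- function(run_activity, position_cm, n_bins = 50,
                                   belt_length_cm = 150, n_shuffles = 1000,
                                   frame_rate_hz = 19, seed = 1L) {
  if (is.null(dim(run_activity)) || nrow(run_activity) == 0 ||
      ncol(run_activity) == 0) {
    return(structure(list(summary = data.frame(), fields = list(),
                          tuning = matrix(0, 0, n_bins)),
                     class = "spatial_cell_results"))
  }
  N <- ncol(run_activity)
  tuning <- matrix(NA_real_, N, n_bins)
  fields <- vector("list", N)
  si <- si_p <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    a <- run_activity[, i]
    tc <- compute_tuning_curve(a, position_cm, n_bins, belt_length_cm)
    tuning[i, ] <- tc$values
    if (all(a == 0) || tc$overall_mean <= 0) {
      si_p[i] <- 1
      fields[[i]] <- list()
      next
    }
    st <- shuffle_test(a, position_cm, n_shuffles = n_shuffles,
                       seed = seed + i, frame_rate_hz = frame_rate_hz,
                       n_bins = n_bins, belt_length_cm = belt_length_cm)
    si[i] <- st$si_bits
    si_p[i] <- st$p_value
    lapmat <- per_lap_matrix(a, position_cm, n_bins, belt_length_cm)
    fields[[i]] <- if (nrow(lapmat) >= 10) detect_place_fields(tc, lapmat)
                   else list()
  }
  n_fields <- vapply(fields, length, integer(1))
  structure(list(
    summary = data.frame(neuron = seq_len(N), si_bits = si, si_p = si_p,
                         n_fields = n_fields,
                         is_spatial = (si_p < 0.05) & (n_fields >= 1)),
    fields = fields,
    tuning = tuning,
    n_bins = n_bins,
    belt_length_cm = belt_length_cm
  ), class = "spatial_cell_results")
}

#' @export
print.spatial_cell_results <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("Spatial-cell classification: %d neurons, %d spatially selective (%.1f%%)\n",
              n, sum(x$summary$is_spatial), 100 * mean(x$summary$is_spatial)))
  invisible(x)
}
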