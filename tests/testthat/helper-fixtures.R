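# Shared fixtures and independent oracles used across test files.

# A small but complete synthetic session (enough laps, enough cue/place
# cells for the default three ensembles).
small_config <- function(seed = 1L, ...) {
  args <- list(n_neurons = 40, frac_place = 0.5, frac_cue = 0.15,
               run_duration_s = 150, rest_duration_s = 180,
               with_lfp = FALSE, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  if (!is.null(extra$n_ensembles) && is.null(extra$n_ensembles_rest1)) {
    args$n_ensembles_rest1 <- min(1, extra$n_ensembles)
  }
  do.call(sim_config, args)
}

# Rest-activity matrix with planted synchronous groups, built directly
# (independent of the package's session generator): each group bursts
# together at its event frames on top of sparse independent background.
planted_rest_matrix <- function(n_neurons, groups, n_events, n_frames,
                                frame_rate = 19, seed = 1L,
                                burst_amp = 2, bg_rate = 0.1) {
  set.seed(seed)
  A <- matrix(0, n_frames, n_neurons)
  env <- c(0.4, 1, 0.7, 0.3)
  # background transients
  p <- bg_rate / frame_rate
  on <- matrix(rbinom(n_frames * n_neurons, 1, p) * runif(n_frames * n_neurons, 0.5, 1.5),
               n_frames, n_neurons)
  for (j in seq_len(n_neurons)) {
    A[, j] <- convolve(on[, j], rev(env), type = "open")[seq_len(n_frames)]
  }
  times <- list()
  for (g in seq_along(groups)) {
    ev <- sort(sample(seq(10, n_frames - 10), n_events))
    times[[g]] <- ev
    for (t0 in ev) {
      idx <- t0:(t0 + length(env) - 1)
      A[idx, groups[[g]]] <- A[idx, groups[[g]]] +
        outer(env, burst_amp * runif(length(groups[[g]]), 0.8, 1.2))
    }
  }
  A <- pmax(A + matrix(rnorm(n_frames * n_neurons, 0, 0.05), n_frames, n_neurons), 0)
  list(activity = A, event_frames = times)
}

# Minimal spatial_cell_results object built from a tuning matrix and a
# spatial flag, for segment-extraction tests.
fake_spatial <- function(tuning, is_spatial, belt_length_cm = 150) {
  n <- nrow(tuning)
  structure(list(
    summary = data.frame(neuron = seq_len(n), si_bits = 1, si_p = 0.01,
                         n_fields = 1L, is_spatial = is_spatial),
    fields = rep(list(list()), n),
    tuning = tuning,
    n_bins = ncol(tuning),
    belt_length_cm = belt_length_cm
  ), class = "spatial_cell_results")
}

# Independent brute-force oracle for the wavelet field candidates: the CWT
# coefficient at (centre, scale) computed by direct summation of the
# circularly wrapped Ricker kernel against the curve.
brute_ricker_coef <- function(values, center, scale) {
  n <- length(values)
  a <- scale
  k <- -n:n
  psi <- 2 / (sqrt(3 * a) * pi^0.25) * (1 - (k / a)^2) * exp(-k^2 / (2 * a^2))
  idx <- ((center - 1 + k) %% n) + 1
  sum(values[idx] * psi)
}

# Exhaustive-enumeration oracle for the upper-tail hypergeometric
# probability P(X >= k): enumerate all size-m draws from N items of which
# K are marked.
enum_hyper_upper <- function(k, m, K, N) {
  draws <- utils::combn(N, m)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Match two event-time lists: fraction of `planted` with a detection within
# tol (hit rate) and fraction of `detected` near a planted time (precision).
match_events <- function(planted, detected, tol) {
  hit <- if (length(planted)) mean(vapply(planted, function(t)
    any(abs(detected - t) <= tol), logical(1))) else NA_real_
  prec <- if (length(detected)) mean(vapply(detected, function(t)
    any(abs(planted - t) <= tol), logical(1))) else NA_real_
  list(hit = hit, precision = prec)
}

# Adjusted Rand index between two integer label vectors (closed form on
# the pair-count contingency table); independent of any clustering code.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
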