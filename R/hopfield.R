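# Hopfield pattern-completion test: can a cue ensemble's reactivated
# spatial feature, presented as a partial probe, retrieve the trajectory
# feature it is temporally coupled with?

#' Binarize a reactivated feature into a +/-1 pattern
#'
#' Bins whose min-max normalized value exceeds `threshold_frac` of the
#' feature's range become +1, the rest -1.
#'
#' @param feature Numeric feature vector over spatial bins.
#' @param threshold_frac Threshold as a fraction of the normalized range
#'   (default 0.5).
#' @return Integer vector of +/-1, class `"binary_pattern"`.
#' @export
binarize_feature <- function(feature, threshold_frac = 0.5) {
  stopifnot(all(is.finite(feature)))
  rng <- range(feature)
  if (diff(rng) <= 0) stop("flat feature cannot be binarized")
  norm <- (feature - rng[1]) / diff(rng)
  structure(ifelse(norm > threshold_frac, 1L, -1L), class = "binary_pattern")
}

#' Train a Hopfield network on binary patterns
#'
#' Hebbian outer-product rule: `W = sum_p x_p x_p' / n`, symmetric with a
#' zero diagonal. Mutually near-orthogonal stored patterns are fixed points
#' of the retrieval dynamics.
#'
#' @param patterns List of +/-1 vectors of equal length.
#' @return Object of class `"hopfield_net"` with `weights` and
#'   `stored_patterns`.
#' @export
hopfield_train <- function(patterns) {
  stopifnot(length(patterns) >= 1)
  n <- length(patterns[[1]])
  stopifnot(all(vapply(patterns, length, integer(1)) == n),
            all(vapply(patterns, function(p) all(p %in% c(-1L, 1L)), logical(1))))
  W <- matrix(0, n, n)
  for (p in patterns) W <- W + tcrossprod(as.numeric(p)) / n
  diag(W) <- 0
  structure(list(weights = W, stored_patterns = patterns),
            class = "hopfield_net")
}

#' Hopfield energy of a state
#'
#' `E = -0.5 * s' W s`; non-increasing under asynchronous updates.
#'
#' @param net A `"hopfield_net"`.
#' @param state +/-1 state vector.
#' @return The scalar energy.
#' @export
hopfield_energy <- function(net, state) {
  s <- as.numeric(state)
  -0.5 * sum(s * (net$weights %*% s))
}

#' Retrieve a stored pattern from a probe
#'
#' Asynchronous sign updates in fixed index order until no bit flips (or
#' `max_sweeps` is reached); a zero local field keeps the current bit.
#'
#' @param net A `"hopfield_net"`.
#' @param probe +/-1 probe vector.
#' @param max_sweeps Maximum full sweeps.
#' @return The settled +/-1 state with attributes `converged` and
#'   `sweeps`.
#' @export
hopfield_retrieve <- function(net, probe, max_sweeps = 100) {
  s <- as.integer(probe)
  n <- length(s)
  stopifnot(nrow(net$weights) == n, all(s %in% c(-1L, 1L)))
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (i in seq_len(n)) {
      h <- sum(net$weights[i, ] * s)
      new <- if (h > 0) 1L else if (h < 0) -1L else s[i]
      if (new != s[i]) { s[i] <- new; changed <- TRUE }
    }
    if (!changed) { converged <- TRUE; break }
  }
  structure(s, class = "binary_pattern", converged = converged,
            sweeps = sweeps)
}

#' Hamming distance between two binary patterns
#'
#' @param a,b +/-1 vectors of equal length.
#' @return Number of differing bits.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(unclass(a) != unclass(b))
}

#' Coupled-retrieval experiment over a session's ensemble pairs
#'
#' For every valid combination of one coupled and one uncoupled trajectory
#' feature from the same session, the network stores the two binarized
#' trajectory features and is probed with the coupled pair's cue feature.
#' A retrieval is successful when the settled state is nearer (Hamming) to
#' the coupled trajectory pattern; equidistant outcomes are indeterminate
#' and counted separately.
#'
#' @param features_cue Cue-ensemble feature matrix (ensembles x bins).
#' @param features_traj Trajectory-ensemble feature matrix.
#' @param pairs A [find_coupled_pairs()] table for these ensembles.
#' @param threshold_frac Binarization threshold.
#' @return List of class `"retrieval_experiment"`: per-combination
#'   `outcomes` data frame, `success_fraction`, and the Hamming distances
#'   between cue features and their coupled / uncoupled trajectory
#'   features.
#' @export
coupled_retrieval_experiment <- function(features_cue, features_traj, pairs,
                                         threshold_frac = 0.5) {
  stopifnot(inherits(pairs, "coupled_pairs") || is.data.frame(pairs))
  coupled <- pairs[pairs$coupled, , drop = FALSE]
  outcomes <- NULL
  ham_coupled <- ham_uncoupled <- numeric(0)
  for (r in seq_len(nrow(coupled))) {
    ci <- coupled$cue_id[r]; tj <- coupled$traj_id[r]
    p_cue <- try(binarize_feature(features_cue[ci, ], threshold_frac), silent = TRUE)
    p_tc <- try(binarize_feature(features_traj[tj, ], threshold_frac), silent = TRUE)
    if (inherits(p_cue, "try-error") || inherits(p_tc, "try-error")) next
    others <- unique(pairs$traj_id[pairs$cue_id == ci & !pairs$coupled])
    for (tu in others) {
      p_tu <- try(binarize_feature(features_traj[tu, ], threshold_frac),
                  silent = TRUE)
      if (inherits(p_tu, "try-error")) next
      if (all(unclass(p_tu) == unclass(p_tc))) {  # degenerate: identical patterns
        outcomes <- rbind(outcomes, data.frame(
          cue_id = ci, coupled_traj = tj, uncoupled_traj = tu,
          result = "indeterminate"))
        next
      }
      net <- hopfield_train(list(p_tc, p_tu))
      settled <- hopfield_retrieve(net, p_cue)
      d_c <- hamming_distance(settled, p_tc)
      d_u <- hamming_distance(settled, p_tu)
      res <- if (d_c < d_u) "coupled" else if (d_u < d_c) "uncoupled"
             else "indeterminate"
      outcomes <- rbind(outcomes, data.frame(
        cue_id = ci, coupled_traj = tj, uncoupled_traj = tu, result = res))
      ham_coupled <- c(ham_coupled, hamming_distance(p_cue, p_tc))
      ham_uncoupled <- c(ham_uncoupled, hamming_distance(p_cue, p_tu))
    }
  }
  decided <- if (is.null(outcomes)) 0 else sum(outcomes$result != "indeterminate")
  succ <- if (decided > 0) sum(outcomes$result == "coupled") / decided else NA_real_
  structure(list(outcomes = outcomes, success_fraction = succ,
                 hamming_coupled = ham_coupled,
                 hamming_uncoupled = ham_uncoupled),
            class = "retrieval_experiment")
}

#' @export
print.retrieval_experiment <- function(x, ...) {
  n <- if (is.null(x$outcomes)) 0 else nrow(x$outcomes)
  cat(sprintf("Pattern-completion experiment: %d combination(s)\n", n))
  if (n > 0) {
    cat(sprintf("  coupled trajectory retrieved in %.1f%% of decided cases\n",
                100 * x$success_fraction))
  }
  invisible(x)
}
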