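# Seeded PCA-ICA reactivation model.
#
# The ensembles found by hierarchical clustering seed an orthonormal basis
# (one unit indicator vector per ensemble). The seed-explained variance is
# subtracted from the standardized rest activity, the residual is screened
# for extra signal components against the Marcenko-Pastur eigenvalue bound,
# and the concatenated basis is refined by reconstruction ICA. Projecting a
# block's activity onto the first M refined components gives each
# ensemble's reactivation strength over time.

#' Build the seed basis from ensemble memberships
#'
#' Column m is the indicator vector of ensemble m's members normalized to
#' unit length: nonzero entries equal `1/sqrt(size)`. Disjoint memberships
#' make the columns orthonormal.
#'
#' @param members List of neuron index sets (disjoint).
#' @param n_neurons Total neuron count.
#' @return Neurons x M matrix with orthonormal columns.
#' @export
build_seed_basis <- function(members, n_neurons) {
  members <- ensemble_members(members)
  stopifnot(length(members) >= 1)
  all_m <- unlist(members)
  if (anyDuplicated(all_m)) {
    stop("ensembles share members; the seed basis requires disjoint sets")
  }
  stopifnot(all(all_m >= 1), all(all_m <= n_neurons))
  W <- matrix(0, n_neurons, length(members))
  for (m in seq_along(members)) {
    W[members[[m]], m] <- 1 / sqrt(length(members[[m]]))
  }
  W
}

#' Remove the seed-explained variance from standardized activity
#'
#' `Xhat = X - X W W'` projects out the subspace spanned by the seed basis,
#' so the residual satisfies `Xhat W = 0`.
#'
#' @param X Frames x neurons standardized activity.
#' @param W Seed basis from [build_seed_basis()].
#' @return The residual matrix.
#' @export
denoise_residual <- function(X, W) {
  stopifnot(ncol(X) == nrow(W))
  X - X %*% W %*% t(W)
}

#' Marcenko-Pastur screening of residual components
#'
#' Eigendecomposition of the residual's second-moment matrix; eigenvectors
#' whose eigenvalues exceed the Marcenko-Pastur upper bound
#' `lambda_+ = (1 + sqrt(N/T))^2` carry structure beyond i.i.d. noise and
#' are kept. By default the (cross-product) covariance of the standardized
#' residual is decomposed, which keeps the retained eigenvectors exactly
#' orthogonal to the seed basis; `use_correlation = TRUE` rescales the
#' residual columns to unit variance first.
#'
#' @param Xhat Residual matrix from [denoise_residual()].
#' @param use_correlation Decompose the correlation instead of the
#'   covariance of the residual.
#' @return List with `eigvals`, `eigvecs`, `lambda_plus`, `kept` (matrix of
#'   retained eigenvectors, possibly 0 columns) and `n_kept`.
#' @export
select_components <- function(Xhat, use_correlation = FALSE) {
  N <- ncol(Xhat)
  Tn <- nrow(Xhat)
  if (Tn <= N) {
    warning("fewer frames than neurons; Marcenko-Pastur bound unreliable")
  }
  sds <- apply(Xhat, 2, stats::sd)
  ok <- is.finite(sds) & sds > 1e-12
  Xw <- Xhat[, ok, drop = FALSE]
  if (use_correlation) Xw <- scale(Xw, center = TRUE, scale = TRUE)
  C <- crossprod(Xw) / (Tn - 1)
  eg <- eigen(C, symmetric = TRUE)
  lambda_plus <- (1 + sqrt(N / Tn))^2
  keep <- which(eg$values > lambda_plus)
  vec_full <- matrix(0, N, length(keep))
  if (length(keep) > 0) vec_full[ok, ] <- eg$vectors[, keep, drop = FALSE]
  list(eigvals = eg$values, eigvecs = eg$vectors, lambda_plus = lambda_plus,
       kept = vec_full, n_kept = length(keep))
}

# Reconstruction-ICA objective and gradient. Rows of X are observations in
# the k-dimensional projected space; g(x) = 0.5 * log(cosh(2x)) is the
# smooth sparsity contrast. Both terms are averaged over rows so the
# balance is independent of the block length.
rica_objective <- function(W, X, penalty_weight) {
  Tn <- nrow(X)
  P <- X %*% W
  E <- X - P %*% t(W)
  recon <- sum(E * E) / Tn
  pen <- penalty_weight * sum(0.5 * log(cosh(2 * P))) / Tn
  recon + pen
}

rica_gradient <- function(W, X, penalty_weight) {
  Tn <- nrow(X)
  P <- X %*% W
  E <- X - P %*% t(W)
  g_recon <- -(crossprod(X, E) %*% W + crossprod(E, X) %*% W) * (2 / Tn)
  g_pen <- penalty_weight * crossprod(X, tanh(2 * P)) / Tn
  g_recon + g_pen
}

#' Refine a projected basis by reconstruction ICA
#'
#' Minimizes the reconstruction error plus the `0.5*log(cosh(2x))` sparsity
#' penalty over the rotation `W`, by gradient descent with backtracking
#' line search from the identity (the data are already projected onto the
#' concatenated seed/PCA basis, so the identity is the natural start).
#'
#' @param Xp Frames x k matrix of activity projected on the concatenated
#'   basis (unit-variance scaled).
#' @param penalty_weight Weight of the sparsity penalty (default 1).
#' @param max_iter Maximum gradient steps.
#' @param tol Relative objective-change tolerance.
#' @return List with the rotation `W`, `objective_trace`, `converged` and
#'   `iterations`.
#' @export
fit_rica <- function(Xp, penalty_weight = 1, max_iter = 500, tol = 1e-6) {
  k <- ncol(Xp)
  W <- diag(k)
  obj <- rica_objective(W, Xp, penalty_weight)
  trace <- obj
  step <- 0.1
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    G <- rica_gradient(W, Xp, penalty_weight)
    gnorm2 <- sum(G * G)
    if (gnorm2 < 1e-20) { converged <- TRUE; break }
    accepted <- FALSE
    for (ls in 1:40) {
      W_new <- W - step * G
      obj_new <- rica_objective(W_new, Xp, penalty_weight)
      if (obj_new <= obj - 1e-4 * step * gnorm2) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (obj - obj_new) / max(abs(obj), 1e-12)
    W <- W_new
    obj <- obj_new
    trace <- c(trace, obj)
    step <- step * 2  # allow the step to grow back
    if (rel < tol) { converged <- TRUE; break }
  }
  list(W = W, objective_trace = trace, converged = converged, iterations = it)
}

#' Fit the seeded PCA-ICA reactivation model
#'
#' The central estimator of the package. Standardizes the rest activity on
#' non-movement frames, builds the seed basis from the ensemble
#' memberships, removes the seed-explained variance, screens the residual
#' for supra-Marcenko-Pastur components, refines the concatenated basis by
#' reconstruction ICA, and extracts the first M refined components (one per
#' ensemble). The per-neuron standardization statistics are stored so RUN
#' or other blocks can be projected into the same component space.
#'
#' @param rest_activity Frames x neurons rest activity (deconvolved rates).
#' @param ensembles An `"ensemble_set"` or list of member index vectors.
#' @param movement_mask Optional logical per-frame movement flag; flagged
#'   frames are excluded from all fitted statistics.
#' @param frame_rate_hz Imaging frame rate.
#' @param penalty_weight,max_iter,tol Reconstruction-ICA controls.
#' @param use_correlation Passed to [select_components()].
#' @return An object of class `"reactivation_model"`.
#' @export
fit_reactivation <- function(rest_activity, ensembles, movement_mask = NULL,
                             frame_rate_hz = 19, penalty_weight = 1,
                             max_iter = 500, tol = 1e-6,
                             use_correlation = FALSE) {
  stopifnot(is.matrix(rest_activity))
  members <- ensemble_members(ensembles)
  if (length(members) == 0) stop("no ensembles to seed the model with")
  N <- ncol(rest_activity)
  Xfit <- rest_activity
  if (!is.null(movement_mask)) {
    stopifnot(length(movement_mask) == nrow(rest_activity))
    Xfit <- rest_activity[!movement_mask, , drop = FALSE]
  }
  Z <- standardize_columns(Xfit)
  center <- attr(Z, "center"); scl <- attr(Z, "scale")

  W_seed <- build_seed_basis(members, N)
  M <- ncol(W_seed)
  Xhat <- denoise_residual(Z, W_seed)
  pca <- select_components(Xhat, use_correlation = use_correlation)
  W_prime <- cbind(W_seed, pca$kept)

  Xp <- Z %*% W_prime
  pscale <- apply(Xp, 2, stats::sd)
  pscale[!is.finite(pscale) | pscale <= 0] <- 1
  ica <- fit_rica(sweep(Xp, 2, pscale, "/"), penalty_weight = penalty_weight,
                  max_iter = max_iter, tol = tol)

  comp <- (W_prime %*% t(ica$W))[, seq_len(M), drop = FALSE]
  for (m in seq_len(M)) {  # sign: largest-magnitude weight positive
    j <- which.max(abs(comp[, m]))
    if (comp[j, m] < 0) comp[, m] <- -comp[, m]
    comp[, m] <- comp[, m] / sqrt(sum(comp[, m]^2))
  }

  model <- structure(list(
    members = members,
    labels = if (inherits(ensembles, "ensemble_set"))
      vapply(ensembles$ensembles, function(e) e$label, character(1))
    else rep(NA_character_, M),
    seed_basis = W_seed,
    pca = pca,
    ica = ica,
    basis = W_prime,
    components = comp,
    center = center,
    scale = scl,
    frame_rate_hz = frame_rate_hz,
    penalty_weight = penalty_weight
  ), class = "reactivation_model")
  model$strength <- reactivation_strength(rest_activity, model)
  model$movement_mask <- movement_mask
  model$events <- lapply(seq_len(M), function(m)
    detect_reactivation_events(model$strength[, m], frame_rate_hz,
                               stat_mask = movement_mask))
  model
}

#' Reactivation strength of each ensemble over time
#'
#' Standardizes a block with the model's rest-fit statistics and projects
#' it onto the refined components.
#'
#' @param X_block Frames x neurons activity of any block.
#' @param model A fitted `"reactivation_model"` (or a components matrix, in
#'   which case `X_block` must already be standardized).
#' @return Frames x M strength matrix.
#' @export
reactivation_strength <- function(X_block, model) {
  if (inherits(model, "reactivation_model")) {
    stopifnot(ncol(X_block) == nrow(model$components))
    Z <- standardize_columns(X_block, model$center, model$scale)
    Z %*% model$components
  } else {
    stopifnot(ncol(X_block) == nrow(model))
    X_block %*% model
  }
}

#' Detect reactivation events in a strength time series
#'
#' Events are excursions above `mu + 3*sd` of the series; each event's
#' onset and offset are pushed outward to the first crossing of 25% of that
#' threshold, and events whose extended bounds overlap are merged.
#'
#' @param strength Numeric strength series (>= 1 min of data).
#' @param frame_rate_hz Frame rate.
#' @param stat_mask Optional logical mask of frames (e.g. movement) to
#'   exclude from the mean/SD estimate.
#' @param n_sd Threshold in SDs above the mean (default 3).
#' @param boundary_frac Fraction of the threshold delimiting onset/offset.
#' @return Data frame with `onset_s`, `offset_s`, `peak_s`, `peak_strength`
#'   (peak in SD units above the mean).
#' @export
detect_reactivation_events <- function(strength, frame_rate_hz = 19,
                                       stat_mask = NULL, n_sd = 3,
                                       boundary_frac = 0.25) {
  if (length(strength) < 60 * frame_rate_hz) {
    stop("need at least one minute of data to estimate event statistics")
  }
  ref <- if (is.null(stat_mask)) strength else strength[!stat_mask]
  mu <- mean(ref); sdv <- stats::sd(ref)
  empty <- data.frame(onset_s = numeric(), offset_s = numeric(),
                      peak_s = numeric(), peak_strength = numeric())
  if (!is.finite(sdv) || sdv <= 0) return(empty)
  theta <- mu + n_sd * sdv
  low <- boundary_frac * theta
  core <- logical_runs(strength > theta)
  if (nrow(core) == 0) return(empty)
  n <- length(strength)
  below <- strength <= low
  bounds <- t(apply(core, 1, function(r) {
    s <- r[["start"]]; e <- r[["end"]]
    pre <- which(below[seq_len(s)])
    post <- which(below[e:n])
    c(if (length(pre)) max(pre) + 1L else 1L,
      if (length(post)) e + min(post) - 2L else n)
  }))
  # merge overlapping extended events
  ord <- order(bounds[, 1])
  bounds <- bounds[ord, , drop = FALSE]
  merged <- list(bounds[1, ])
  for (i in seq_len(nrow(bounds))[-1]) {
    last <- merged[[length(merged)]]
    if (bounds[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], bounds[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- bounds[i, ]
    }
  }
  out <- do.call(rbind, lapply(merged, function(b) {
    seg <- strength[b[1]:b[2]]
    pk <- b[1] + which.max(seg) - 1L
    data.frame(onset_s = (b[1] - 1) / frame_rate_hz,
               offset_s = (b[2] - 1) / frame_rate_hz,
               peak_s = (pk - 1) / frame_rate_hz,
               peak_strength = (strength[pk] - mu) / sdv)
  }))
  rownames(out) <- NULL
  out
}

#' Reactivated spatial features of each ensemble
#'
#' Projects the RUN block into the model's component space and averages
#' each ensemble's strength over the 50 spatial bins, giving the spatial
#' feature the ensemble reactivates for.
#'
#' @param model A fitted `"reactivation_model"`.
#' @param run_activity Frames x neurons RUN activity.
#' @param position_cm Per-frame position.
#' @param n_bins,belt_length_cm Spatial binning.
#' @return Matrix (ensembles x bins) of class `"reactivated_features"`.
#' @export
extract_run_features <- function(model, run_activity, position_cm,
                                 n_bins = 50, belt_length_cm = 150) {
  stopifnot(inherits(model, "reactivation_model"))
  S <- reactivation_strength(run_activity, model)
  bins <- pmin(floor(position_cm / belt_length_cm * n_bins) + 1L, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  grp <- factor(bins, levels = which(counts > 0))
  means <- rowsum(S, grp) / counts[counts > 0]
  out <- matrix(0, ncol(S), n_bins)
  out[, counts > 0] <- t(means)
  structure(out, class = c("reactivated_features", "matrix"))
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.reactivation_model <- function(x, ...) {
  cat("Seeded PCA-ICA reactivation model\n")
  cat(sprintf("  %d ensembles, %d residual PCA component(s) above lambda_+ = %.3f\n",
              length(x$members), x$pca$n_kept, x$pca$lambda_plus))
  cat(sprintf("  reconstruction ICA: %d iteration(s), %s\n",
              x$ica$iterations,
              if (x$ica$converged) "converged" else "stopped at max_iter"))
  n_ev <- vapply(x$events, nrow, integer(1))
  cat(sprintf("  reactivation events per ensemble: %s\n",
              paste(n_ev, collapse = ", ")))
  invisible(x)
}

#' @export
summary.reactivation_model <- function(object, ...) {
  n_ev <- vapply(object$events, nrow, integer(1))
  dur_s <- nrow(object$strength) / object$frame_rate_hz
  df <- data.frame(
    ensemble = seq_along(object$members),
    label = object$labels,
    size = vapply(object$members, length, integer(1)),
    n_events = n_ev,
    event_rate_hz = n_ev / dur_s,
    peak_z = vapply(object$events, function(e)
      if (nrow(e)) max(e$peak_strength) else NA_real_, numeric(1))
  )
  structure(list(table = df, pca = object$pca,
                 ica_converged = object$ica$converged),
            class = "summary.reactivation_model")
}

#' @export
print.summary.reactivation_model <- function(x, ...) {
  cat("Reactivation model summary\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.reactivation_model <- function(object, ...) object$components

#' Project new activity into a fitted model's component space
#'
#' @param object A `"reactivation_model"`.
#' @param newdata Frames x neurons activity block.
#' @param type `"strength"` for the projected time series, `"events"` to
#'   also run the event detector on it.
#' @param ... Passed to [detect_reactivation_events()] for
#'   `type = "events"`.
#' @return Strength matrix, or list of event tables.
#' @export
predict.reactivation_model <- function(object, newdata, type = c("strength", "events"),
                                       ...) {
  type <- match.arg(type)
  S <- reactivation_strength(newdata, object)
  if (type == "strength") return(S)
  lapply(seq_len(ncol(S)), function(m)
    detect_reactivation_events(S[, m], object$frame_rate_hz, ...))
}

#' Plot reactivation strength traces with detected events
#'
#' @param x A `"reactivation_model"`.
#' @param ensembles Which ensembles to draw (default all).
#' @param ... Further graphical parameters.
#' @export
plot.reactivation_model <- function(x, ensembles = seq_along(x$members), ...) {
  tt <- (seq_len(nrow(x$strength)) - 1) / x$frame_rate_hz
  old <- graphics::par(mfrow = c(length(ensembles), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (m in ensembles) {
    graphics::plot(tt, x$strength[, m], type = "l",
                   xlab = "time (s)", ylab = sprintf("ensemble %d", m), ...)
    ev <- x$events[[m]]
    if (nrow(ev)) graphics::points(ev$peak_s,
                                   x$strength[round(ev$peak_s * x$frame_rate_hz) + 1, m],
                                   col = 2, pch = 19)
  }
  invisible(x)
}
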