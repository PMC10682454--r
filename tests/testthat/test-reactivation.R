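# The seeded PCA-ICA reactivation model: seed basis, residual denoising,
# Marcenko-Pastur screening, reconstruction ICA, strengths and events.

test_that("the seed basis is the unit-normalized membership indicator", {
  W <- build_seed_basis(list(1:4, 5:13), 20)
  expect_equal(unique(W[1:4, 1]), 0.5)
  expect_equal(unique(W[5:13, 2]), 1 / 3)
  expect_equal(crossprod(W), diag(2), tolerance = 1e-12)
  # a single all-neuron ensemble: one column of 1/sqrt(N)
  W1 <- build_seed_basis(list(1:20), 20)
  expect_equal(unique(W1[, 1]), 1 / sqrt(20))
  # overlap violates the orthonormality premise
  expect_error(build_seed_basis(list(1:5, 5:9), 20), "disjoint")
})

test_that("denoising removes exactly the seed subspace", {
  set.seed(1)
  W <- build_seed_basis(list(1:5, 6:12), 30)
  # columns inside span(W): residual vanishes
  X_in <- matrix(rnorm(200 * 2), 200, 2) %*% t(W)
  expect_equal(max(abs(denoise_residual(X_in, W))), 0, tolerance = 1e-10)
  # random X: residual is orthogonal to the basis, energies add up
  X <- matrix(rnorm(200 * 30), 200, 30)
  Xh <- denoise_residual(X, W)
  expect_lt(max(abs(Xh %*% W)), 1e-8)
  expect_equal(sum(X^2), sum((X %*% W %*% t(W))^2) + sum(Xh^2),
               tolerance = 1e-6 * sum(X^2))
  expect_error(denoise_residual(X[, 1:10], W))
})

test_that("Marcenko-Pastur screening keeps signal and drops noise", {
  expect_equal((1 + sqrt(100 / 10000))^2, 1.21)  # closed form of the bound
  set.seed(2)
  noise <- scale(matrix(rnorm(5000 * 50), 5000, 50))
  sel <- select_components(noise)
  expect_equal(sel$lambda_plus, (1 + sqrt(50 / 5000))^2)
  expect_lte(sel$n_kept, 1)
  # one planted global component far above the bound: exactly one kept
  g <- rnorm(5000)
  planted <- scale(noise + outer(g, rep(1, 50)))
  sel2 <- select_components(planted)
  expect_identical(sel2$n_kept, 1L)
  expect_lt(max(abs(crossprod(sel2$kept) - diag(1))), 1e-8)
})

test_that("the rica objective and gradient are mutually consistent", {
  set.seed(3)
  X <- matrix(rnorm(60 * 4), 60, 4)
  W <- diag(4) + matrix(rnorm(16, 0, 0.05), 4, 4)
  G <- restreact:::rica_gradient(W, X, penalty_weight = 1)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(4, 2))) {
    Wp <- W; Wp[idx[1], idx[2]] <- Wp[idx[1], idx[2]] + eps
    Wm <- W; Wm[idx[1], idx[2]] <- Wm[idx[1], idx[2]] - eps
    num <- (restreact:::rica_objective(Wp, X, 1) -
              restreact:::rica_objective(Wm, X, 1)) / (2 * eps)
    expect_equal(G[idx[1], idx[2]], num, tolerance = 1e-4)
  }
})

test_that("at the identity start the objective is pure penalty", {
  set.seed(4)
  X <- matrix(rnorm(500 * 3), 500, 3)
  pen <- sum(0.5 * log(cosh(2 * X))) / nrow(X)
  expect_equal(restreact:::rica_objective(diag(3), X, 1), pen,
               tolerance = 1e-10)
})

test_that("reconstruction ICA unmixes orthogonally mixed sparse sources", {
  set.seed(5)
  Tn <- 4000
  S <- matrix(rnorm(Tn * 3)^3, Tn, 3)       # heavy-tailed sparse sources
  S <- scale(S)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))     # random orthogonal mixing
  X <- S %*% Q
  fit <- fit_rica(scale(X), max_iter = 500)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
  rec <- scale(X) %*% fit$W
  cc <- abs(cor(rec, S))
  # each source recovered by some component up to sign/permutation
  expect_true(all(apply(cc, 2, max) >= 0.9))
})

test_that("the refined basis stays orthonormal and strengths are z-scaled", {
  cfg <- small_config(seed = 13L, rest_duration_s = 300)
  sim <- simulate_full_experiment(cfg)
  s <- sim$session
  mod <- fit_reactivation(s$rest2, sim$truth$ensemble_members,
                          s$movement_mask$rest2)
  expect_lt(max(abs(crossprod(mod$basis) - diag(ncol(mod$basis)))), 1e-8)
  expect_equal(vapply(seq_along(mod$members), function(m)
    sqrt(sum(mod$components[, m]^2)), numeric(1)),
    rep(1, length(mod$members)), tolerance = 1e-10)
  # strengths over non-movement frames have near-zero mean
  S <- mod$strength[!s$movement_mask$rest2, ]
  expect_lt(max(abs(colMeans(S))), 0.2)
  # sign convention: dominant weight positive
  for (m in seq_along(mod$members)) {
    expect_gt(mod$components[which.max(abs(mod$components[, m])), m], 0)
  }
})

test_that("strength projection respects zero weights and zero activity", {
  comp <- build_seed_basis(list(1:5), 10)
  Z <- matrix(rnorm(500 * 10), 500, 10)
  s0 <- reactivation_strength(Z, comp)
  # neurons outside the component cannot move the strength
  Z2 <- Z; Z2[, 6:10] <- Z2[, 6:10] + 100
  expect_equal(reactivation_strength(Z2, comp), s0, tolerance = 1e-10)
  expect_equal(reactivation_strength(matrix(0, 100, 10), comp),
               matrix(0, 100, 1))
})

test_that("event detection finds supra-threshold excursions only", {
  fr <- 19
  n <- 80 * fr
  set.seed(6)
  base <- runif(n, -0.5, 0.5)   # bounded noise: never crosses 3 SD alone
  expect_identical(nrow(detect_reactivation_events(rep(1, n), fr)), 0L)
  # a large bump produces exactly one event containing the peak
  bump <- 10 * exp(-((seq_len(n) - 800) / 4)^2 / 2)
  ev <- detect_reactivation_events(base + bump, fr)
  expect_identical(nrow(ev), 1L)
  expect_lte(ev$onset_s, 799 / fr)
  expect_gte(ev$offset_s, 799 / fr)
  expect_gt(ev$peak_strength, 3)
  # a bump peaking near 2 SD stays below threshold
  small <- 2 * sd(base) * exp(-((seq_len(n) - 800) / 4)^2 / 2)
  expect_identical(nrow(detect_reactivation_events(base + small, fr)), 0L)
  expect_error(detect_reactivation_events(rnorm(100), fr), "minute")
})

test_that("ICA refinement does not lose planted events versus the seed basis", {
  cfg <- small_config(seed = 14L, rest_duration_s = 300,
                      reactivation_rate_hz = 0.05)
  sim <- simulate_full_experiment(cfg)
  s <- sim$session; tr <- sim$truth
  mod <- fit_reactivation(s$rest2, tr$ensemble_members, s$movement_mask$rest2)
  Z <- restreact:::standardize_columns(s$rest2, mod$center, mod$scale)
  seed_strength <- Z %*% mod$seed_basis
  for (m in seq_along(tr$ensemble_members)) {
    planted <- tr$reactivation_times_s$rest2[[m]]
    if (length(planted) < 5) next
    ev_seed <- detect_reactivation_events(seed_strength[, m], 19,
                                          stat_mask = s$movement_mask$rest2)
    hits_seed <- match_events(planted, ev_seed$onset_s, 0.3)$hit
    hits_ica <- match_events(planted, mod$events[[m]]$onset_s, 0.3)$hit
    expect_gte(hits_ica, hits_seed)
  }
})

test_that("model methods expose the fit coherently", {
  cfg <- small_config(seed = 15L, rest_duration_s = 240)
  sim <- simulate_full_experiment(cfg)
  mod <- fit_reactivation(sim$session$rest2, sim$truth$ensemble_members,
                          sim$session$movement_mask$rest2)
  expect_equal(dim(coef(mod)),
               c(cfg$n_neurons, length(sim$truth$ensemble_members)))
  sm <- summary(mod)
  expect_identical(nrow(sm$table), length(sim$truth$ensemble_members))
  S_run <- predict(mod, sim$session$run)
  expect_identical(dim(S_run), c(nrow(sim$session$run),
                                 length(sim$truth$ensemble_members)))
  feats <- extract_run_features(mod, sim$session$run, sim$session$position_cm)
  expect_identical(dim(unclass(feats)),
                   c(length(sim$truth$ensemble_members), 50L))
  expect_true(all(is.finite(feats)))
})
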