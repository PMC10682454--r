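# Peri-event timing, lag estimation, coupled pairs, feature similarity,
# explained variance and persistence statistics.

test_that("peri-event averages align impulse trains at lag zero", {
  fr <- 19
  n <- 120 * fr
  events <- c(20, 45, 70, 95)
  series <- numeric(n)
  series[round(events * fr) + 1] <- 1
  pea <- peri_event_average(series, events, fr, window_s = 1)
  expect_equal(pea$lags_s[which.max(pea$mean_z)], 0)
  expect_identical(pea$n_events, 4L)
  # a single event reproduces its own (z-scored) window
  pea1 <- peri_event_average(series, events[1], fr, window_s = 1)
  z <- as.numeric(scale(series))
  c0 <- round(events[1] * fr) + 1
  expect_equal(pea1$mean_z, z[(c0 - fr):(c0 + fr)])
  expect_error(peri_event_average(series, 1000, fr), "window")
})

test_that("gaussian-fitted cross-correlation recovers planted lags", {
  fr <- 19
  set.seed(1)
  a <- restreact:::gauss_smooth(rnorm(4000), 2)
  expect_lt(abs(xcorr_gaussian_lag(a, a, fr)$lag_s), 0.01)
  # a 2-frame shift (105 ms) is recovered within one frame
  b <- c(rep(0, 2), a[1:(length(a) - 2)])
  est <- xcorr_gaussian_lag(a, b, fr)
  expect_lt(abs(est$lag_s - 2 / fr), 1 / fr)
  # antisymmetry under argument swap
  est_rev <- xcorr_gaussian_lag(b, a, fr)
  expect_lt(abs(est$lag_s + est_rev$lag_s), 0.02)
})

test_that("onset cross-correlograms localize constant offsets", {
  set.seed(2)
  b <- sort(runif(40, 10, 290))
  xc0 <- onset_crosscorrelogram(b, b, bin_ms = 100, n_boot = 100)
  expect_equal(xc0$lag_centers_s[which.max(xc0$counts)], 0, tolerance = 0.06)
  a <- b + 0.25
  xc <- onset_crosscorrelogram(a, b, bin_ms = 100, n_boot = 100)
  expect_equal(xc$lag_centers_s[which.max(xc$counts)], 0.25, tolerance = 0.06)
  expect_error(onset_crosscorrelogram(1:3, b))
})

test_that("coupled pairs are flagged against the circular-shift null", {
  fr <- 19
  set.seed(3)
  n <- 4000
  # co-reactivating pair: shared impulses, trajectory delayed ~100 ms
  impulses <- numeric(n)
  impulses[sample(100:(n - 100), 40)] <- runif(40, 1, 2)
  cue <- restreact:::gauss_smooth(impulses + rnorm(n, 0, 0.05), 2)
  traj <- restreact:::gauss_smooth(c(rep(0, 2), impulses[1:(n - 2)]) +
                                     rnorm(n, 0, 0.05), 2)
  indep <- restreact:::gauss_smooth(rnorm(n), 2)
  pr <- find_coupled_pairs(cbind(cue), cbind(traj, indep), fr,
                           n_null = 300, seed = 4L)
  expect_true(pr$coupled[1])
  expect_lt(abs(pr$lag_s[1] - 2 / fr), 0.15)
  expect_false(pr$coupled[2])
  # identical series: coupled at lag ~0
  pr_id <- find_coupled_pairs(cbind(cue), cbind(cue), fr, n_null = 300,
                              seed = 5L)
  expect_true(pr_id$coupled[1])
  expect_lt(abs(pr_id$lag_s[1]), 0.06)
})

test_that("the coupling null is calibrated under independence", {
  fr <- 19
  set.seed(6)
  n_pairs <- 60
  hits <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- restreact:::gauss_smooth(rnorm(1500), 2)
    b <- restreact:::gauss_smooth(rnorm(1500), 2)
    hits[i] <- find_coupled_pairs(cbind(a), cbind(b), fr, n_null = 200,
                                  seed = i)$coupled[1]
  }
  # false-positive rate compatible with alpha = 0.05 (binomial 3 SE band)
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / n_pairs))
})

test_that("feature similarity behaves at the extremes", {
  f <- c(rep(0, 40), 1:10)
  expect_equal(feature_similarity(f, f)$r, 1)
  expect_equal(feature_similarity(f, -f)$r, -1)
  expect_true(feature_similarity(f, rep(2, 50))$degenerate)
})

test_that("SWR association fractions match the Poisson closed form", {
  expect_equal(swr_association_fraction(c(1, 2, 3), numeric(0)), 0)
  expect_equal(swr_association_fraction(c(10.1, 50.1), c(10, 50), 0.5), 100)
  # Poisson SWRs at rate lambda: expected fraction 1 - exp(-2*lambda*w)
  set.seed(7)
  lam <- 0.2; w <- 0.5
  fracs <- replicate(40, {
    swr <- cumsum(rexp(300, lam))
    swr <- swr[swr < 1000]
    evs <- runif(150, 0, 1000)
    swr_association_fraction(evs, swr, w) / 100
  })
  expect_equal(mean(fracs), 1 - exp(-2 * lam * w), tolerance = 0.03)
})

test_that("explained variance detects re-expressed RUN structure", {
  set.seed(8)
  n <- 20; Tn <- 2000
  latent <- matrix(rnorm(Tn * 4), Tn, 4)
  load <- matrix(rnorm(4 * n), 4, n)
  run <- latent %*% load + matrix(rnorm(Tn * n, 0, 0.5), Tn, n)
  rest2 <- matrix(rnorm(Tn * 4), Tn, 4) %*% load +
    matrix(rnorm(Tn * n, 0, 0.5), Tn, n)     # same correlation structure
  rest1 <- matrix(rnorm(Tn * n), Tn, n)       # independent
  ev <- explained_variance(rest1, run, rest2)
  expect_gt(ev$ev_percent, 50)
  expect_lt(ev$rev_percent, 10)
  expect_true(ev$ev_percent <= 100 && ev$rev_percent >= 0)
  # swapping the rest epochs swaps ev and rev exactly
  sw <- explained_variance(rest2, run, rest1)
  expect_equal(sw$ev_percent, ev$rev_percent, tolerance = 1e-10)
  expect_equal(sw$rev_percent, ev$ev_percent, tolerance = 1e-10)
  expect_error(explained_variance(rest1[, 1:3], run[, 1:3], rest2[, 1:3]))
})

test_that("jaccard persistence follows set arithmetic", {
  expect_equal(jaccard_persistence(1:6, 1:6), 1)
  expect_equal(jaccard_persistence(1:5, 6:10), 0)
  expect_equal(jaccard_persistence(1:6, 4:9), 1 / 3)
  expect_error(jaccard_persistence(integer(0), integer(0)))
  expect_equal(max_jaccard(1:6, list(7:12, 4:9, 1:2)), 1 / 3)
  expect_equal(max_jaccard(1:6, list()), 0)
})

test_that("persistence significance agrees with exact enumeration", {
  # complete overlap in a small universe is persistent even at alpha 0.001
  ps <- persistence_significance(8, 8, 8, 20)
  expect_true(ps$persistent)
  expect_equal(ps$p_value, 1 / choose(20, 8), tolerance = 1e-10)
  # overlap at chance expectation is not significant
  ps2 <- persistence_significance(2, 5, 8, 20)   # E[O] = 2
  expect_false(ps2$persistent)
  expect_gt(ps2$p_value, 0.5)
  # zero overlap can never be persistent
  expect_false(persistence_significance(0, 5, 5, 20)$persistent)
  expect_error(persistence_significance(6, 5, 8, 20))
})
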