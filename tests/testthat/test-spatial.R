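# Spatial tuning, spatial information and place-field detection.

# Position trace visiting all 50 bins uniformly (4 frames per bin).
uniform_position <- function(frames_per_bin = 4) {
  rep((0:49) * 3 + 1.5, each = frames_per_bin)
}

test_that("tuning curves are occupancy-weighted bin means", {
  pos <- uniform_position()
  tc <- compute_tuning_curve(rep(1, length(pos)), pos)
  expect_equal(tc$values, rep(1, 50))
  expect_equal(tc$occupancy, rep(0.02, 50))

  act <- as.numeric(pos < 3)
  tc2 <- compute_tuning_curve(act, pos)
  expect_equal(which(tc2$values > 0), 1L)
  # unvisited bins are flagged, not imputed
  pos3 <- pos[pos < 140]
  tc3 <- compute_tuning_curve(rep(1, length(pos3)), pos3)
  expect_true(all(is.na(tc3$values[48:50])))
})

test_that("spatial information matches its closed forms", {
  pos <- uniform_position()
  # single active bin, uniform occupancy: I = log2(50)
  one <- compute_tuning_curve(as.numeric(pos < 3), pos)
  expect_equal(spatial_information(one), log2(50), tolerance = 1e-9)
  # two equal active bins: I = log2(25)
  two <- compute_tuning_curve(as.numeric(pos < 6), pos)
  expect_equal(spatial_information(two), log2(25), tolerance = 1e-9)
  # uniform activity: I = 0
  flat <- compute_tuning_curve(rep(2, length(pos)), pos)
  expect_equal(spatial_information(flat), 0, tolerance = 1e-12)
  # silent neuron: undefined
  expect_error(spatial_information(compute_tuning_curve(rep(0, length(pos)), pos)))
})

test_that("spatial information is non-negative and rotation invariant", {
  set.seed(11)
  pos <- uniform_position()
  for (i in 1:20) {
    act <- rgamma(length(pos), 0.5, 1)
    tc <- compute_tuning_curve(act, pos)
    si <- spatial_information(tc)
    expect_gte(si, -1e-12)
    # joint circular rotation of (values, occupancy) leaves I unchanged
    k <- sample(49, 1)
    rot <- tc
    rot$values <- c(tc$values[-(1:k)], tc$values[1:k])
    rot$occupancy <- c(tc$occupancy[-(1:k)], tc$occupancy[1:k])
    expect_equal(spatial_information(rot), si, tolerance = 1e-12)
  }
})

test_that("the circular-shuffle test is calibrated at the extremes", {
  pos <- rep(uniform_position(), 10)
  # constant activity carries no information: never significant
  st <- shuffle_test(rep(3, length(pos)), pos, n_shuffles = 100, seed = 1)
  expect_equal(st$si_bits, 0, tolerance = 1e-12)
  expect_equal(st$p_value, 1)
  # silent neuron: p = 1 by convention
  expect_equal(shuffle_test(rep(0, length(pos)), pos, n_shuffles = 100,
                            seed = 1)$p_value, 1)
  # a strong place cell is significant (irregularly sampled positions so
  # the circular shift genuinely breaks the place relation)
  set.seed(12)
  pos_r <- runif(2000, 0, 150)
  act <- exp(-((pos_r - 75) / 8)^2) + abs(rnorm(length(pos_r), 0, 0.02))
  expect_lt(shuffle_test(act, pos_r, n_shuffles = 200, seed = 2)$p_value, 0.05)
})

test_that("place fields are found where bumps are and nowhere else", {
  pos <- uniform_position()
  gauss_curve <- function(center_bin, sd_bins, amp = 1) {
    b <- 1:50
    d <- pmin(abs(b - center_bin), 50 - abs(b - center_bin))
    amp * exp(-d^2 / (2 * sd_bins^2))
  }
  mk_laps <- function(curve, n_laps = 12) {
    t(replicate(n_laps, curve + abs(rnorm(50, 0, 0.02))))
  }
  mk_tc <- function(curve) {
    structure(list(values = curve, occupancy = rep(0.02, 50),
                   overall_mean = mean(curve), n_bins = 50,
                   belt_length_cm = 150), class = "tuning_curve")
  }
  set.seed(3)
  # flat: nothing
  expect_length(detect_place_fields(mk_tc(rep(1, 50)), mk_laps(rep(1, 50))), 0)
  # one bump at bin 25
  c1 <- gauss_curve(25, 4)
  f1 <- detect_place_fields(mk_tc(c1), mk_laps(c1))
  expect_length(f1, 1)
  expect_true(25 %in% f1[[1]]$bins)
  # two bumps
  c2 <- gauss_curve(10, 3) + gauss_curve(40, 3)
  f2 <- detect_place_fields(mk_tc(c2), mk_laps(c2))
  expect_length(f2, 2)
  centers <- sort(vapply(f2, function(f) f$center_bin, numeric(1)))
  expect_true(all(abs(centers - c(10, 40)) <= 2))
  # session-inclusion rule: fewer than 10 laps is an error
  expect_error(detect_place_fields(mk_tc(c1), mk_laps(c1)[1:8, ]),
               "10 laps")
})

test_that("wavelet coefficients agree with direct brute-force evaluation", {
  set.seed(8)
  v <- exp(-((1:50 - 20)^2) / 18) + 0.3 * exp(-((1:50 - 42)^2) / 8) +
    abs(rnorm(50, 0, 0.03))
  W <- restreact:::ricker_cwt(v, 1:50)
  for (sc in c(2, 5, 11, 25)) {
    for (ctr in c(1, 20, 42, 50)) {
      expect_equal(W[sc, ctr], brute_ricker_coef(v, ctr, sc),
                   tolerance = 1e-8)
    }
  }
  # the dominant detected candidate sits at the brute-force optimum
  grid <- expand.grid(center = 1:50, scale = 2:20)
  coefs <- mapply(brute_ricker_coef, grid$center, grid$scale,
                  MoreArgs = list(values = v))
  best <- grid[which.max(coefs), ]
  laps <- t(replicate(12, v))
  tc <- structure(list(values = v, occupancy = rep(0.02, 50),
                       overall_mean = mean(v), n_bins = 50,
                       belt_length_cm = 150), class = "tuning_curve")
  f <- detect_place_fields(tc, laps)
  expect_gt(length(f), 0)
  d <- abs(f[[1]]$center_bin - best$center)
  expect_lte(min(d, 50 - d), 1)
})

test_that("classification composes the two criteria", {
  cfg <- small_config(seed = 6L)
  run <- simulate_run(cfg)
  sp <- classify_spatial_cells(run$activity, run$position_cm,
                               n_shuffles = 200, seed = 3L)
  expect_equal(nrow(sp$summary), cfg$n_neurons)
  expect_identical(sp$summary$is_spatial,
                   (sp$summary$si_p < 0.05) & (sp$summary$n_fields >= 1))
  # empty session: empty result
  empty <- classify_spatial_cells(matrix(0, 0, 0), numeric(0))
  expect_identical(nrow(empty$summary), 0L)
})
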