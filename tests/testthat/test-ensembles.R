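# Ensemble detection, trajectory segments, classification, encoding bias
# and composition enrichment.

test_that("correlation distance maps correlation onto [0, 2]", {
  set.seed(1)
  base <- abs(rnorm(2000))
  X <- cbind(base, base, -base + max(base), rnorm(2000), rnorm(2000))
  dm <- correlation_distance(X, sigma_ms = 0)
  expect_equal(dm$d[1, 2], 0, tolerance = 1e-12)          # identical
  expect_equal(dm$d[1, 3], 2, tolerance = 1e-12)          # anti-correlated
  expect_identical(diag(dm$d), rep(0, 5))
  expect_true(isSymmetric(dm$d))
  # constant trace is flagged out
  Xc <- cbind(X, 1)
  dmc <- correlation_distance(Xc, sigma_ms = 0)
  expect_false(dmc$valid[6])
  expect_true(all(is.na(dmc$d[6, -6])))
})

test_that("independent long traces sit near distance 1", {
  set.seed(2)
  X <- matrix(rnorm(1e4 * 6), ncol = 6)
  dm <- correlation_distance(X, sigma_ms = 0)
  off <- dm$d[upper.tri(dm$d)]
  expect_true(all(abs(off - 1) < 0.05))
})

test_that("planted synchronous groups are recovered exactly", {
  groups <- list(1:6, 7:14, 15:24)   # sizes 6, 8, 10
  pl <- planted_rest_matrix(40, groups, n_events = 25, n_frames = 6000,
                            seed = 3L)
  dm <- correlation_distance(pl$activity)
  es <- detect_ensembles(dm)
  planted <- rep(0L, 40); for (g in seq_along(groups)) planted[groups[[g]]] <- g
  det <- rep(0L, 40)
  for (m in seq_along(es$ensembles)) det[es$ensembles[[m]]$members] <- m
  expect_gte(adjusted_rand(planted, det), 0.9)
  # every reported ensemble respects the cutoff-implied mean correlation
  for (e in es$ensembles) {
    sub <- 1 - dm$d[e$members, e$members]
    expect_gte(mean(sub[upper.tri(sub)]), 0.25)
  }
})

test_that("groups below the membership minimum are not ensembles", {
  pl <- planted_rest_matrix(20, list(1:4), n_events = 25, n_frames = 6000,
                            seed = 4L)
  es <- detect_ensembles(correlation_distance(pl$activity))
  expect_identical(length(es), 0L)
  # and fully independent populations yield nothing either
  set.seed(5)
  noise <- matrix(abs(rnorm(4000 * 15, 0, 0.3)), ncol = 15)
  expect_identical(length(detect_ensembles(correlation_distance(noise))), 0L)
})

test_that("clustering is invariant to neuron ordering", {
  groups <- list(2:7, 10:16)
  pl <- planted_rest_matrix(25, groups, n_events = 20, n_frames = 5000,
                            seed = 6L)
  es1 <- detect_ensembles(correlation_distance(pl$activity))
  set.seed(7); perm <- sample(25)
  es2 <- detect_ensembles(correlation_distance(pl$activity[, perm]))
  sets1 <- lapply(restreact:::ensemble_members(es1), sort)
  sets2 <- lapply(restreact:::ensemble_members(es2), function(m) sort(perm[m]))
  expect_setequal(sapply(sets1, paste, collapse = ","),
                  sapply(sets2, paste, collapse = ","))
})

test_that("trajectory segments follow the members' supra-threshold tuning", {
  bump <- function(center_bin, sd_bins) {
    b <- 1:50
    d <- pmin(abs(b - center_bin), 50 - abs(b - center_bin))
    exp(-d^2 / (2 * sd_bins^2))
  }
  # 5 members with identical narrow bumps at 30 cm (bin 10)
  tun <- t(replicate(5, bump(10, 2)))
  sp <- fake_spatial(tun, rep(TRUE, 5))
  seg <- extract_trajectory_segments(1:5, sp)
  expect_identical(nrow(seg), 1L)
  expect_true(seg$start_cm <= 30 && seg$end_cm >= 30)
  expect_lt(seg$length_cm, 20)
  # members tiling 40-80 cm: one segment spanning roughly that range
  centers <- seq(14, 27, length.out = 6)   # bins for 40-80 cm
  tun2 <- t(sapply(centers, bump, sd_bins = 2))
  sp2 <- fake_spatial(tun2, rep(TRUE, 6))
  seg2 <- extract_trajectory_segments(1:6, sp2)
  expect_identical(nrow(seg2), 1L)
  expect_lt(abs(seg2$start_cm - 40), 9)
  expect_lt(abs(seg2$end_cm - 80), 9)
  # fewer than 3 spatially-selective members: no segments
  sp3 <- fake_spatial(tun, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(nrow(extract_trajectory_segments(1:5, sp3)), 0L)
})

test_that("segments wrapped across the reward line are handled circularly", {
  b <- 1:50
  d <- pmin(abs(b - 1), 50 - abs(b - 1))       # bump centred at bin 1 (0 cm)
  tun <- t(replicate(4, exp(-d^2 / 8)))
  sp <- fake_spatial(tun, rep(TRUE, 4))
  seg <- extract_trajectory_segments(1:4, sp)
  expect_identical(nrow(seg), 1L)
  expect_true(seg$wrapped)
  expect_equal(classify_ensemble(seg, cue_centers_cm = 0), "cue")
})

test_that("the cue-first labelling rule is applied", {
  seg_cue <- data.frame(start_cm = 22, end_cm = 38, length_cm = 16,
                        wrapped = FALSE, n_cells = 4L)
  expect_equal(classify_ensemble(seg_cue, cue_centers_cm = 30), "cue")
  seg_long <- data.frame(start_cm = 40, end_cm = 80, length_cm = 40,
                         wrapped = FALSE, n_cells = 5L)
  expect_equal(classify_ensemble(seg_long, cue_centers_cm = 30), "trajectory")
  expect_equal(classify_ensemble(seg_long[0, ], cue_centers_cm = 30), "none")
  # both a qualifying cue segment and a long one: cue wins
  both <- rbind(seg_long, seg_cue)
  expect_equal(classify_ensemble(both, cue_centers_cm = 30), "cue")
  # a short segment away from every cue is still a trajectory
  seg_off <- data.frame(start_cm = 60, end_cm = 75, length_cm = 15,
                        wrapped = FALSE, n_cells = 3L)
  expect_equal(classify_ensemble(seg_off, cue_centers_cm = 30), "trajectory")
})

test_that("encoding bias separates place-like from cue-like neurons", {
  cfg <- small_config(seed = 12L, noise_sd = 0.02)
  run <- simulate_run(cfg)
  cues <- cfg$cue_centers_cm
  # a place cell far from all cues leans place (negative ratio)
  pc <- which(run$truth$cell_labels == "place")
  far <- pc[vapply(run$truth$field_centers_cm[pc], function(c0)
    min(restreact:::circ_dist(c0, cues, 150)) > 15, logical(1))][1]
  eb_place <- encoding_bias(run$activity[, far], run$position_cm, cues)
  expect_lt(eb_place$ratio, 0)
  # a cue cell leans cue (positive ratio)
  cc <- which(run$truth$cell_labels == "cue")[1]
  eb_cue <- encoding_bias(run$activity[, cc], run$position_cm, cues)
  expect_gt(eb_cue$ratio, 0)
  expect_gt(eb_cue$ratio, eb_place$ratio)
  # silent neurons are rejected
  expect_error(encoding_bias(rep(0, nrow(run$activity)), run$position_cm, cues),
               "silent")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  expect_equal(hypergeometric_enrichment(5, 5, 5, 10), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometric_enrichment(0, 5, 5, 10), 1)
  for (case in list(c(2, 4, 5, 10), c(3, 6, 6, 12), c(1, 3, 4, 9))) {
    expect_equal(hypergeometric_enrichment(case[1], case[2], case[3], case[4]),
                 enum_hyper_upper(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-10)
  }
  expect_error(hypergeometric_enrichment(6, 5, 5, 10))
})
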