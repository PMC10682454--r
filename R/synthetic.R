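# Synthetic session generator.
#
# Produces REST1/RUN/REST2 session bundles with planted ground truth: place
# and cue cells with known tuning, co-active resting ensembles with known
# membership and reactivation times, hippocampal SWR bursts on a simulated
# LFP, and configurable onset lags between SWRs and the reactivations of the
# two ensemble classes. Every downstream stage of the pipeline is validated
# by recovering these planted parameters.

#' Configuration for a synthetic imaging session
#'
#' Defaults mirror the acquisition conditions the pipeline targets: a 150 cm
#' circular treadmill belt carrying four visuo-tactile cues, ~19 Hz
#' two-photon frame rate, LFP analysed at 2.6 kHz, and 10-20 min rest blocks
#' flanking the run. The reactivation transient envelope is ~180 ms, the
#' median event duration the detector is tuned to recover.
#'
#' @param n_neurons Number of simultaneously imaged neurons.
#' @param frac_place Fraction of neurons given Gaussian place tuning.
#' @param frac_cue Fraction of neurons responding at every cue location.
#' @param belt_length_cm Belt length in cm.
#' @param cue_centers_cm Positions of the cue centres in cm (the last two
#'   default to being close together, as on the physical belt).
#' @param cue_width_cm Spatial footprint of a cue response in cm.
#' @param frame_rate_hz Imaging frame rate.
#' @param lfp_rate_hz LFP sampling rate.
#' @param run_duration_s,rest_duration_s Block durations in seconds.
#' @param n_ensembles Number of co-active ensembles planted in REST2.
#' @param n_ensembles_rest1 How many of those ensembles also reactivate in
#'   REST1 (fewer, matching the sparser pre-task rest).
#' @param ensemble_size_range Min/max ensemble membership.
#' @param reactivation_rate_hz Poisson rate of reactivation events per
#'   ensemble during rest.
#' @param swr_rate_hz Poisson rate of sharp-wave ripples during rest.
#' @param p_swr_coupled Probability that a reactivation event is time-locked
#'   to an SWR.
#' @param cue_lag_ms,traj_lag_ms Planted onset lag of cue / trajectory
#'   ensemble reactivations relative to the coupled SWR onset.
#' @param noise_sd SD of additive Gaussian activity noise (deconvolved
#'   event-rate units; traces are clipped at zero).
#' @param background_rate_hz Rate of spontaneous background transients per
#'   neuron during rest (and for untuned neurons during run).
#' @param movement_frac Fraction of rest frames flagged as movement epochs.
#' @param run_speed_cms Mean running speed in cm/s.
#' @param place_field_sd_cm SD of the Gaussian place tuning in cm.
#' @param swr_amp_sd Amplitude of planted ripple bursts, in SDs of the
#'   background ripple-band envelope.
#' @param with_lfp Generate the LFP traces (disable for imaging-only runs).
#' @param seed Integer RNG seed; a fixed seed makes the whole session
#'   bit-identical across calls.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_neurons = 100,
                       frac_place = 0.35,
                       frac_cue = 0.10,
                       belt_length_cm = 150,
                       cue_centers_cm = c(22.5, 52.5, 97.5, 120),
                       cue_width_cm = 9,
                       frame_rate_hz = 19,
                       lfp_rate_hz = 2600,
                       run_duration_s = 480,
                       rest_duration_s = 600,
                       n_ensembles = 3,
                       n_ensembles_rest1 = 1,
                       ensemble_size_range = c(6, 10),
                       reactivation_rate_hz = 0.04,
                       swr_rate_hz = 0.08,
                       p_swr_coupled = 0.5,
                       cue_lag_ms = 50,
                       traj_lag_ms = 180,
                       noise_sd = 0.05,
                       background_rate_hz = 0.10,
                       movement_frac = 0.08,
                       run_speed_cms = 15,
                       place_field_sd_cm = 8,
                       swr_amp_sd = 5,
                       with_lfp = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  stopifnot(
    n_neurons >= 1, run_duration_s > 0, rest_duration_s > 0,
    frac_place >= 0, frac_cue >= 0, frac_place + frac_cue <= 1,
    belt_length_cm > 0, cue_width_cm > 0,
    all(cue_centers_cm >= 0), all(cue_centers_cm < belt_length_cm),
    frame_rate_hz > 0, lfp_rate_hz > 0,
    n_ensembles >= 0, n_ensembles_rest1 >= 0, n_ensembles_rest1 <= n_ensembles,
    length(ensemble_size_range) == 2, ensemble_size_range[1] >= 5,
    ensemble_size_range[1] <= ensemble_size_range[2],
    reactivation_rate_hz >= 0, swr_rate_hz >= 0,
    p_swr_coupled >= 0, p_swr_coupled <= 1,
    noise_sd >= 0, background_rate_hz >= 0,
    movement_frac >= 0, movement_frac < 1,
    run_speed_cms > 0, place_field_sd_cm > 0, swr_amp_sd > 0
  )
  structure(cfg, class = "sim_config")
}

# ~180 ms transient envelope: half-Gaussian rise then half-Gaussian decay,
# peak 1. Returned at the imaging frame rate.
transient_envelope <- function(frame_rate_hz, duration_s = 0.18) {
  len <- max(3L, round(duration_s * frame_rate_hz))
  peak <- ceiling(len / 3)
  rise <- exp(-((peak - seq_len(peak)) / (peak / 2))^2 / 2)
  dec_len <- len - peak
  decay <- exp(-((seq_len(dec_len)) / (dec_len / 1.8))^2 / 2)
  c(rise, decay)
}

# Sparse background transients: per-frame Bernoulli onsets convolved with
# the transient envelope, amplitudes U(0.5, 1.5).
sparse_transients <- function(n_frames, n_neurons, rate_hz, frame_rate_hz) {
  p <- min(1, rate_hz / frame_rate_hz)
  env <- transient_envelope(frame_rate_hz)
  A <- matrix(0, n_frames, n_neurons)
  if (p <= 0 || n_neurons == 0) return(A)
  onsets <- matrix(stats::rbinom(n_frames * n_neurons, 1, p) *
                     stats::runif(n_frames * n_neurons, 0.5, 1.5),
                   n_frames, n_neurons)
  for (j in which(colSums(onsets) > 0)) {
    conv <- stats::convolve(onsets[, j], rev(env), type = "open")
    A[, j] <- conv[seq_len(n_frames)]
  }
  A
}

#' Simulate the RUN block of a session
#'
#' Place cells emit Gaussian-tuned rates around a field centre; cue cells
#' emit rates peaked within the cue footprint at every cue on every lap;
#' untuned neurons emit sparse background transients. The animal advances at
#' a jittered constant speed and pauses 1 s at the reward line on each lap.
#' Trajectory-ensemble members are given field centres that tile a
#' contiguous segment of the belt; cue-ensemble members are drawn from the
#' cue cells, so planted ensembles have the tuning structure their labels
#' promise.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list with `activity` (frames x neurons), `position_cm`,
#'   `velocity` (cm/s per frame) and `truth`, the ground-truth fragment
#'   (cell labels, field centres, ensemble membership and labels).
#' @export
simulate_run <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  N <- config$n_neurons
  fr <- config$frame_rate_hz
  L <- config$belt_length_cm
  n_frames <- round(config$run_duration_s * fr)

  # --- cell labels -------------------------------------------------------
  n_place <- as.integer(round(config$frac_place * N))
  n_cue <- as.integer(round(config$frac_cue * N))
  labels <- rep("none", N)
  place_ids <- seq_len(n_place)
  cue_ids <- if (n_cue > 0) n_place + seq_len(n_cue) else integer()
  labels[place_ids] <- "place"
  labels[cue_ids] <- "cue"

  # --- ensembles ---------------------------------------------------------
  M <- config$n_ensembles
  ens_members <- list()
  ens_labels <- character()
  centers <- rep(NA_real_, N)
  if (n_place > 0) centers[place_ids] <- stats::runif(n_place, 0, L)
  if (M > 0) {
    n_cue_ens <- max(1L, round(M / 3))
    n_cue_ens <- min(n_cue_ens, M)
    sizes <- sample(seq(config$ensemble_size_range[1],
                        config$ensemble_size_range[2]), M, replace = TRUE)
    avail_cue <- cue_ids
    avail_place <- place_ids
    for (m in seq_len(M)) {
      is_cue <- m <= n_cue_ens
      if (is_cue) {
        sizes[m] <- min(sizes[m], length(avail_cue))
        if (sizes[m] < 5)
          stop("not enough cue cells for the requested cue ensembles")
        mem <- sort(avail_cue[seq_len(sizes[m])])
        avail_cue <- setdiff(avail_cue, mem)
        ens_labels <- c(ens_labels, "cue")
      } else {
        sizes[m] <- min(sizes[m], length(avail_place))
        if (sizes[m] < 5)
          stop("not enough place cells for the requested trajectory ensembles")
        mem <- sort(avail_place[seq_len(sizes[m])])
        avail_place <- setdiff(avail_place, mem)
        # members tile a contiguous segment of the belt
        seg_len <- stats::runif(1, 30, 40)
        seg_start <- stats::runif(1, 0, L)
        centers[mem] <- (seg_start + seq(0, seg_len, length.out = length(mem))) %% L
        ens_labels <- c(ens_labels, "trajectory")
      }
      ens_members[[m]] <- mem
    }
  }

  # --- behaviour: jittered constant-speed laps with a 1 s reward pause ---
  position <- numeric(n_frames)
  velocity <- numeric(n_frames)
  pos <- 0
  pause_left <- 0L
  pause_frames <- round(1 * fr)
  dt <- 1 / fr
  speed_jitter <- gauss_smooth(stats::rnorm(n_frames, 0, 0.15), fr / 2)
  for (t in seq_len(n_frames)) {
    if (pause_left > 0L) {
      pause_left <- pause_left - 1L
      v <- 0
    } else {
      v <- config$run_speed_cms * max(0.2, 1 + speed_jitter[t])
      pos <- pos + v * dt
      if (pos >= L) {
        pos <- pos - L
        pause_left <- pause_frames
      }
    }
    position[t] <- pos
    velocity[t] <- v
  }

  # --- activity ----------------------------------------------------------
  amp <- stats::runif(N, 0.8, 1.2)
  act <- sparse_transients(n_frames, N, config$background_rate_hz, fr)
  act[, labels != "none"] <- 0  # tuned cells carry tuning, not background
  sig_p <- config$place_field_sd_cm
  sig_c <- config$cue_width_cm / 2
  for (i in which(labels == "place")) {
    act[, i] <- amp[i] * exp(-circ_dist(position, centers[i], L)^2 / (2 * sig_p^2))
  }
  if (length(cue_ids) > 0) {
    cue_rate <- rep(0, n_frames)
    for (cc in config$cue_centers_cm) {
      cue_rate <- pmax(cue_rate, exp(-circ_dist(position, cc, L)^2 / (2 * sig_c^2)))
    }
    for (i in cue_ids) act[, i] <- amp[i] * cue_rate
  }
  act <- act + matrix(stats::rnorm(n_frames * N, 0, config$noise_sd), n_frames, N)
  act <- pmax(act, 0)

  truth <- list(
    cell_labels = labels,
    field_centers_cm = centers,
    ensemble_members = ens_members,
    ensemble_labels = ens_labels,
    # reactivation bursts stand out ~2x above typical background transients,
    # with +/-20% per-member amplitude jitter so the ICA weighting is
    # non-degenerate
    member_amps = lapply(ens_members, function(mem)
      2 * stats::runif(length(mem), 0.8, 1.2)),
    planted_lags_ms = list(cue = config$cue_lag_ms, trajectory = config$traj_lag_ms)
  )
  list(activity = act, position_cm = position, velocity = velocity, truth = truth)
}

#' Simulate a rest block with planted ensemble reactivations
#'
#' Background activity is independent sparse transients plus Gaussian noise.
#' At each planted reactivation time every member of one ensemble emits an
#' ~180 ms transient (per-member amplitude jittered +/-20% so the ensemble
#' weighting is non-degenerate). If SWR times are supplied, a configurable
#' fraction of events is time-locked to an SWR onset at the class-specific
#' planted lag.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth fragment from [simulate_run()].
#' @param block `"rest1"` or `"rest2"`; REST1 expresses only the first
#'   `n_ensembles_rest1` ensembles.
#' @param swr_times Optional SWR onset times (s) on this block's clock.
#' @param seed Optional override of the block-specific seed.
#' @return List with `activity`, logical `movement_mask`,
#'   `reactivation_times` (list per planted ensemble; ensembles silent in
#'   this block get `numeric(0)`), and `coupled` flags per event.
#' @export
simulate_rest <- function(config, truth, block = c("rest2", "rest1"),
                          swr_times = NULL,
                          seed = config$seed + ifelse(block[1] == "rest1", 1L, 2L)) {
  stopifnot(inherits(config, "sim_config"))
  block <- match.arg(block)
  set.seed(seed)
  N <- config$n_neurons
  fr <- config$frame_rate_hz
  dur <- config$rest_duration_s
  n_frames <- round(dur * fr)
  env <- transient_envelope(fr)
  env_dur <- length(env) / fr

  M_all <- length(truth$ensemble_members)
  active <- if (block == "rest1") seq_len(min(config$n_ensembles_rest1, M_all))
            else seq_len(M_all)

  # movement epochs: ~2 s bouts until the target fraction is reached
  movement <- rep(FALSE, n_frames)
  target <- round(config$movement_frac * n_frames)
  guard <- 0L
  while (sum(movement) < target && guard < 1000L) {
    len <- round(stats::runif(1, 1, 3) * fr)
    s <- sample.int(max(1L, n_frames - len), 1)
    movement[s:(s + len - 1L)] <- TRUE
    guard <- guard + 1L
  }

  react_times <- rep(list(numeric(0)), M_all)
  coupled <- rep(list(logical(0)), M_all)
  min_gap <- 2 * env_dur + 0.5
  for (m in active) {
    lab <- truth$ensemble_labels[m]
    lag_s <- truth$planted_lags_ms[[if (lab == "cue") "cue" else "trajectory"]] / 1000
    n_ev <- stats::rpois(1, config$reactivation_rate_hz * dur)
    if (n_ev == 0) next
    if (n_ev * min_gap > 0.8 * dur) {
      stop("reactivation_rate_hz too high to place non-overlapping events")
    }
    is_cpl <- if (!is.null(swr_times) && length(swr_times) > 0)
      stats::runif(n_ev) < config$p_swr_coupled else rep(FALSE, n_ev)
    times <- rep(NA_real_, n_ev)
    n_cpl <- sum(is_cpl)
    if (n_cpl > 0) {
      usable <- swr_times[swr_times > 1 & swr_times < dur - 1]
      n_cpl <- min(n_cpl, length(usable))
      is_cpl[which(is_cpl)[seq_len(sum(is_cpl)) > n_cpl]] <- FALSE
      if (n_cpl > 0) {
        picked <- sort(usable[sample.int(length(usable), n_cpl)])
        times[which(is_cpl)] <- picked + lag_s
      }
    }
    ok_frames <- which(!movement)
    for (k in which(!is_cpl)) {
      for (try in 1:200) {
        cand <- ok_frames[sample.int(length(ok_frames), 1)] / fr
        if (cand < 1 || cand > dur - 1) next
        if (all(abs(cand - times) >= min_gap, na.rm = TRUE)) {
          times[k] <- cand
          break
        }
      }
      if (is.na(times[k])) {
        stop("reactivation_rate_hz too high to place non-overlapping events")
      }
    }
    ord <- order(times)
    react_times[[m]] <- times[ord]
    coupled[[m]] <- is_cpl[ord]
  }

  act <- sparse_transients(n_frames, N, config$background_rate_hz, fr)
  for (m in active) {
    mem <- truth$ensemble_members[[m]]
    amps <- truth$member_amps[[m]]
    for (tt in react_times[[m]]) {
      f0 <- round(tt * fr) + 1L
      idx <- f0:(f0 + length(env) - 1L)
      keep <- idx >= 1 & idx <= n_frames
      ev_scale <- stats::runif(1, 0.8, 1.2)
      act[idx[keep], mem] <- act[idx[keep], mem] +
        outer(env[keep], amps * ev_scale)
    }
  }
  act <- act + matrix(stats::rnorm(n_frames * N, 0, config$noise_sd), n_frames, N)
  act <- pmax(act, 0)

  list(activity = act, movement_mask = movement,
       reactivation_times = react_times, coupled = coupled)
}

#' Simulate a hippocampal LFP trace with planted ripple bursts
#'
#' Pink-noise (1/f) background plus, at each SWR time, a ~50 ms
#' Gaussian-enveloped 200 Hz burst whose ripple-band envelope peaks at a
#' configurable number of SDs above the background envelope.
#'
#' @param config A [sim_config()].
#' @param swr_times Burst onset times in seconds.
#' @param duration_s Trace duration (default the rest-block duration).
#' @param burst_freq_hz Carrier frequency of the bursts.
#' @param burst_dur_s Burst duration (Gaussian envelope support).
#' @param seed RNG seed.
#' @return Numeric voltage trace sampled at `config$lfp_rate_hz`.
#' @export
simulate_lfp <- function(config, swr_times, duration_s = config$rest_duration_s,
                         burst_freq_hz = 200, burst_dur_s = 0.05,
                         seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(all(swr_times >= 0), all(swr_times <= duration_s))
  set.seed(seed)
  rate <- config$lfp_rate_hz
  n <- round(duration_s * rate)

  # pink-noise background via 1/sqrt(f) spectral shaping
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freq <- c(1, seq_len(n - 1))
  freq <- pmin(freq, n - freq + 1)  # symmetric frequency index
  spec <- spec / sqrt(freq)
  pink <- Re(stats::fft(spec, inverse = TRUE)) / n
  pink <- pink / stats::sd(pink)

  # calibrate burst amplitude against background ripple-band envelope
  ref_len <- min(n, 30 * rate)
  bg_band <- bandpass_ripple(pink[seq_len(ref_len)], rate)
  bg_env <- rms_envelope(bg_band, rate)
  mu <- mean(bg_env); sdv <- stats::sd(bg_env)
  # the burst must clear swr_amp_sd SDs above the background mean even when
  # it interferes destructively with the background ripple band, so budget
  # one extra background-mean of amplitude on top of the target level
  target_env <- mu + config$swr_amp_sd * sdv + mu
  amp <- target_env * sqrt(2)  # RMS of a sinusoid is amp/sqrt(2)

  burst_n <- round(burst_dur_s * rate)
  tt <- seq_len(burst_n) / rate
  envelope <- exp(-((tt - burst_dur_s / 2) / (burst_dur_s / 4))^2 / 2)
  carrier <- sin(2 * pi * burst_freq_hz * tt)
  burst <- amp * envelope * carrier
  out <- pink
  for (t0 in swr_times) {
    i0 <- round(t0 * rate) + 1L
    idx <- i0:(i0 + burst_n - 1L)
    keep <- idx >= 1 & idx <= n
    out[idx[keep]] <- out[idx[keep]] + burst[keep]
  }
  out
}

# Poisson SWR onset times in (margin, dur - margin), thinned to a minimum
# separation and kept out of movement epochs.
draw_swr_times <- function(config, movement, seed) {
  set.seed(seed)
  dur <- config$rest_duration_s
  fr <- config$frame_rate_hz
  n <- stats::rpois(1, config$swr_rate_hz * dur)
  if (n == 0) return(numeric(0))
  times <- sort(stats::runif(n, 1, dur - 1))
  keep <- c(TRUE, diff(times) >= 0.4)
  times <- times[keep]
  frames <- pmin(length(movement), round(times * fr) + 1L)
  times[!movement[frames]]
}

#' Simulate a complete REST1/RUN/REST2 session
#'
#' Composes [simulate_run()], [simulate_rest()] and [simulate_lfp()].
#' Cue-ensemble reactivations that are SWR-coupled onset `cue_lag_ms` after
#' the SWR onset and trajectory-ensemble reactivations `traj_lag_ms` after,
#' so downstream lag estimators can be validated against the planted
#' difference.
#'
#' @param config A [sim_config()].
#' @return A list with `session` (class `"session_bundle"`) and `truth`
#'   (class `"ground_truth"`).
#' @export
simulate_full_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  run <- simulate_run(config, seed = config$seed)
  truth <- run$truth

  # movement masks are drawn inside simulate_rest; draw SWRs against a
  # provisional mask, then pass them in (events avoid movement epochs).
  r1_seed <- config$seed + 1L
  r2_seed <- config$seed + 2L
  n_rest <- round(config$rest_duration_s * config$frame_rate_hz)
  swr1 <- draw_swr_times(config, rep(FALSE, n_rest), seed = config$seed + 11L)
  swr2 <- draw_swr_times(config, rep(FALSE, n_rest), seed = config$seed + 12L)
  rest1 <- simulate_rest(config, truth, "rest1", swr_times = swr1, seed = r1_seed)
  rest2 <- simulate_rest(config, truth, "rest2", swr_times = swr2, seed = r2_seed)

  lfp <- NULL
  if (config$with_lfp) {
    lfp <- list(
      rest1 = simulate_lfp(config, swr1, seed = config$seed + 13L),
      rest2 = simulate_lfp(config, swr2, seed = config$seed + 14L)
    )
  }

  truth$swr_times_s <- list(rest1 = swr1, rest2 = swr2)
  truth$reactivation_times_s <- list(rest1 = rest1$reactivation_times,
                                     rest2 = rest2$reactivation_times)
  truth$reactivation_coupled <- list(rest1 = rest1$coupled,
                                     rest2 = rest2$coupled)
  class(truth) <- "ground_truth"

  session <- structure(list(
    rest1 = rest1$activity,
    run = run$activity,
    rest2 = rest2$activity,
    position_cm = run$position_cm,
    velocity = run$velocity,
    movement_mask = list(rest1 = rest1$movement_mask,
                         rest2 = rest2$movement_mask),
    lfp = lfp,
    meta = config
  ), class = "session_bundle")

  list(session = session, truth = truth)
}

#' @export
print.session_bundle <- function(x, ...) {
  cfg <- x$meta
  cat("Synthetic imaging session\n")
  cat(sprintf("  neurons: %d   frame rate: %.1f Hz   belt: %g cm\n",
              ncol(x$run), cfg$frame_rate_hz, cfg$belt_length_cm))
  cat(sprintf("  REST1 %d frames | RUN %d frames | REST2 %d frames\n",
              nrow(x$rest1), nrow(x$run), nrow(x$rest2)))
  cat(sprintf("  LFP: %s\n", if (is.null(x$lfp)) "absent"
              else sprintf("present (%.0f Hz)", cfg$lfp_rate_hz)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic session configuration\n")
  cat(sprintf("  %d neurons (%.0f%% place, %.0f%% cue), %d ensembles, seed %d\n",
              x$n_neurons, 100 * x$frac_place, 100 * x$frac_cue,
              x$n_ensembles, x$seed))
  invisible(x)
}
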