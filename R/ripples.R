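# Sharp-wave-ripple detection in hippocampal LFP: 150-250 Hz zero-phase FIR
# bandpass, 8 ms RMS envelope, 3 SD threshold with 75%-of-threshold
# onset/offset bounds, a 3-cycle minimum duration and a 250 ms refractory
# rule.

#' Zero-phase ripple-band filtering of an LFP trace
#'
#' Applies a 400-order FIR bandpass (150-250 Hz by default) forwards and
#' backwards so the filtered trace has no phase shift.
#'
#' @param lfp Voltage trace.
#' @param rate_hz Sampling rate (>= 1 kHz for ripple-band work).
#' @param band Passband edges in Hz.
#' @param order FIR filter order.
#' @return Filtered trace of the same length.
#' @export
bandpass_ripple <- function(lfp, rate_hz, band = c(150, 250), order = 400) {
  stopifnot(rate_hz >= 1000, band[1] < band[2], band[2] < rate_hz / 2)
  if (length(lfp) < 3 * order) {
    stop("LFP trace shorter than 3 x the filter order")
  }
  b <- as.numeric(signal::fir1(order, band / (rate_hz / 2), type = "pass"))
  signal::filtfilt(b, 1, lfp)
}

#' RMS power envelope with a sliding window
#'
#' Centred root-mean-square of the filtered trace over an 8 ms (default)
#' window.
#'
#' @param filtered Ripple-band filtered trace.
#' @param rate_hz Sampling rate.
#' @param window_ms Window length in ms.
#' @return Envelope of the same length.
#' @export
rms_envelope <- function(filtered, rate_hz, window_ms = 8) {
  w <- max(2L, round(window_ms / 1000 * rate_hz))
  sq <- filtered^2
  n <- length(sq)
  # centred running mean via cumulative sums (edges use the partial window)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- c(0, cumsum(sq))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  sqrt(pmax((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L), 0))
}

#' Detect sharp-wave ripples
#'
#' Core regions are where the envelope exceeds `mu + 3*sd`; regions that do
#' not sustain the threshold for at least 3 ripple cycles
#' (3/`ripple_freq_hz`) are rejected, and the survivors' onsets and
#' offsets are pushed outward to the crossings of 75% of the threshold. An event starting less than 250 ms after the previous event's
#' onset is merged into it (or discarded when `refractory = "discard"`).
#' Thresholds are SD-relative, so the detector is invariant to the overall
#' gain of the recording.
#'
#' @param envelope RMS envelope from [rms_envelope()].
#' @param filtered Ripple-band filtered trace (used for cycle counting).
#' @param rate_hz Sampling rate.
#' @param ripple_freq_hz Nominal ripple frequency for the minimum-duration
#'   rule (band centre, 200 Hz).
#' @param min_cycles Minimum event duration in ripple cycles.
#' @param refractory_s Minimum onset-to-onset separation.
#' @param refractory One of `"merge"` (default: a too-close event extends
#'   the previous one) or `"discard"`.
#' @param count_cycles If `TRUE`, the minimum-duration rule counts actual
#'   zero crossings of the filtered trace inside the event instead of using
#'   the nominal frequency.
#' @param stat_mask Optional logical mask (TRUE = exclude) on envelope
#'   samples for the mean/SD estimate, e.g. movement epochs.
#' @return Data frame of class `"ripple_events"`: `onset_s`, `offset_s`,
#'   `peak_s`, `peak_power_sd`.
#' @export
detect_swr <- function(envelope, filtered, rate_hz, ripple_freq_hz = 200,
                       min_cycles = 3, refractory_s = 0.25,
                       refractory = c("merge", "discard"),
                       count_cycles = FALSE, stat_mask = NULL) {
  refractory <- match.arg(refractory)
  ref <- if (is.null(stat_mask)) envelope else envelope[!stat_mask]
  mu <- mean(ref); sdv <- stats::sd(ref)
  empty <- data.frame(onset_s = numeric(), offset_s = numeric(),
                      peak_s = numeric(), peak_power_sd = numeric())
  class(empty) <- c("ripple_events", "data.frame")
  if (!is.finite(sdv) || sdv <= 0) return(empty)
  theta <- mu + 3 * sdv
  low <- 0.75 * theta
  core <- logical_runs(envelope > theta)
  if (nrow(core) == 0) return(empty)
  n <- length(envelope)

  # bridge sub-cycle dips below threshold inside one ripple burst
  if (nrow(core) > 1) {
    bridged <- core[1, , drop = FALSE]
    for (i in 2:nrow(core)) {
      gap <- (core$start[i] - bridged$end[nrow(bridged)] - 1) / rate_hz
      if (gap < 1 / ripple_freq_hz) {
        bridged$end[nrow(bridged)] <- core$end[i]
      } else {
        bridged <- rbind(bridged, core[i, ])
      }
    }
    core <- bridged
  }

  # minimum duration: 3 ripple cycles sustained above threshold, either at
  # the nominal band-centre frequency or by counting zero crossings of the
  # band-passed trace inside the supra-threshold region
  keep <- vapply(seq_len(nrow(core)), function(i) {
    s <- core$start[i]; e <- core$end[i]
    if (count_cycles) {
      seg <- filtered[s:e]
      zc <- sum(diff(sign(seg)) != 0)
      zc / 2 >= min_cycles
    } else {
      (e - s + 1) / rate_hz >= min_cycles / ripple_freq_hz
    }
  }, logical(1))
  core <- core[keep, , drop = FALSE]
  if (nrow(core) == 0) return(empty)

  below <- envelope <= low
  bounds <- t(apply(core, 1, function(r) {
    s <- r[["start"]]; e <- r[["end"]]
    pre <- which(below[seq_len(s)])
    post <- which(below[e:n])
    c(if (length(pre)) max(pre) + 1L else 1L,
      if (length(post)) e + min(post) - 2L else n)
  }))
  ord <- order(bounds[, 1])
  bounds <- unique(bounds[ord, , drop = FALSE])
  # merge events whose extended bounds overlap
  merged <- list(bounds[1, ])
  for (i in seq_len(nrow(bounds))[-1]) {
    last <- merged[[length(merged)]]
    if (bounds[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], bounds[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- bounds[i, ]
    }
  }
  bounds <- do.call(rbind, merged)
  if (nrow(bounds) == 0) return(empty)

  # refractory rule on onsets
  out <- list(bounds[1, ])
  for (i in seq_len(nrow(bounds))[-1]) {
    last <- out[[length(out)]]
    if ((bounds[i, 1] - last[1]) / rate_hz < refractory_s) {
      if (refractory == "merge") {
        out[[length(out)]] <- c(last[1], max(last[2], bounds[i, 2]))
      }  # "discard": drop it
    } else {
      out[[length(out) + 1L]] <- bounds[i, ]
    }
  }
  res <- do.call(rbind, lapply(out, function(b) {
    seg <- envelope[b[1]:b[2]]
    pk <- b[1] + which.max(seg) - 1L
    data.frame(onset_s = (b[1] - 1) / rate_hz,
               offset_s = (b[2] - 1) / rate_hz,
               peak_s = (pk - 1) / rate_hz,
               peak_power_sd = (envelope[pk] - mu) / sdv)
  }))
  rownames(res) <- NULL
  class(res) <- c("ripple_events", "data.frame")
  res
}

#' Full SWR detection from a raw LFP trace
#'
#' Convenience wrapper: bandpass, envelope, detect.
#'
#' @param lfp Raw LFP trace.
#' @param rate_hz Sampling rate.
#' @param ... Passed to [detect_swr()].
#' @return A `"ripple_events"` data frame.
#' @export
find_ripples <- function(lfp, rate_hz, ...) {
  filt <- bandpass_ripple(lfp, rate_hz)
  env <- rms_envelope(filt, rate_hz)
  detect_swr(env, filt, rate_hz, ...)
}
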