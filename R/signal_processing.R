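# Evoked-EMG preprocessing: from raw synchronized eEMG/torque streams to the
# per-stimulation-loop feature series (MAV of the M-wave, mean torque) that
# the online estimators consume.

#' Construct a raw FES recording
#'
#' Bundles the two synchronized analog channels (evoked EMG in mV and the
#' dynamometer analog torque in V, both sampled at `f_samp`) together with the
#' stimulation pulse schedule. Pulses are emitted once per stimulation loop;
#' during rest segments the commanded pulse width is 0 microseconds and no
#' physical pulse is delivered, but the loop clock keeps running.
#'
#' @param emg numeric vector, evoked EMG samples (mV).
#' @param torque_voltage numeric vector, dynamometer analog samples (V); same
#'   length as `emg`.
#' @param f_samp sampling rate in Hz (the reference hardware uses 4096 Hz).
#' @param pulse_times stimulation loop onset times in seconds, strictly
#'   increasing and (nearly) equally spaced at `1/f_stim`.
#' @param pulse_widths commanded pulse width in microseconds, one per pulse,
#'   each within `[0, pw_max]`.
#' @param pw_max stimulator pulse-width limit in microseconds (default 350).
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(emg, torque_voltage, f_samp, pulse_times,
                          pulse_widths, pw_max = 350) {
  emg <- as.numeric(emg)
  torque_voltage <- as.numeric(torque_voltage)
  pulse_times <- as.numeric(pulse_times)
  pulse_widths <- as.numeric(pulse_widths)
  if (length(emg) != length(torque_voltage)) {
    stopf("emg and torque_voltage must have equal length")
  }
  if (!is.numeric(f_samp) || length(f_samp) != 1L || f_samp <= 0) {
    stopf("f_samp must be a positive scalar (Hz)")
  }
  if (length(pulse_times) == 0L) {
    stopf("no stimulation events")
  }
  if (length(pulse_widths) != length(pulse_times)) {
    stopf("pulse_widths must match pulse_times in length")
  }
  if (any(diff(pulse_times) <= 0)) {
    stopf("pulse_times must be strictly increasing")
  }
  if (length(pulse_times) > 1L) {
    gaps <- diff(pulse_times)
    g0 <- median(gaps)
    if (any(abs(gaps - g0) > 0.01 * g0)) {
      stopf("pulse gaps deviate from the stimulation period by more than 1%%")
    }
  }
  if (any(pulse_widths < 0 | pulse_widths > pw_max)) {
    stopf("pulse_widths must lie in [0, pw_max]")
  }
  loop_s <- if (length(pulse_times) > 1L) {
    median(diff(pulse_times))
  } else {
    NA_real_
  }
  if (!is.na(loop_s)) {
    span <- f_samp * (pulse_times[length(pulse_times)] + loop_s)
    need <- ceiling(span - 1e-9 * max(1, span))
    if (length(emg) < need) {
      stopf("recording truncated: %d samples present, %d required",
            length(emg), need)
    }
  }
  structure(
    list(emg = emg, torque_voltage = torque_voltage, f_samp = f_samp,
         pulse_times = pulse_times, pulse_widths = pulse_widths,
         pw_max = pw_max),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d samples @ %g Hz (%.2f s), %d pulses, PW %g-%g us\n",
    length(x$emg), x$f_samp, length(x$emg) / x$f_samp,
    length(x$pulse_times), min(x$pulse_widths), max(x$pulse_widths)
  ))
  invisible(x)
}

#' Segment a recording into per-loop sample ranges
#'
#' Each stimulation loop spans from the sample nearest its pulse onset to the
#' start of the next pulse (half-open); the last loop gets the nominal loop
#' length `round(f_samp / f_stim)` samples. Ranges tile the stimulated span
#' without gaps or overlap. Indices are 0-based to match the loop index `k`.
#'
#' @param rec a [raw_recording()].
#' @param f_stim stimulation frequency in Hz; derived from the median pulse
#'   gap when omitted (required for single-pulse recordings).
#' @return integer matrix with columns `start`, `end` (0-based, half-open),
#'   one row per pulse.
#' @export
segment_loops <- function(rec, f_stim = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  pt <- rec$pulse_times
  if (length(pt) == 0L) stopf("no stimulation events")
  if (is.null(f_stim)) {
    if (length(pt) < 2L) {
      stopf("f_stim required to segment a single-pulse recording")
    }
    f_stim <- 1 / median(diff(pt))
  }
  onsets <- round_half_up(pt * rec$f_samp)
  loop_n <- round_half_up(rec$f_samp / f_stim)
  ends <- c(onsets[-1L], onsets[length(onsets)] + loop_n)
  if (ends[length(ends)] > length(rec$emg)) {
    stopf("recording truncated: loop ends at sample %d, recording has %d",
          ends[length(ends)], length(rec$emg))
  }
  cbind(start = onsets, end = ends)
}

#' Blank the stimulation artifact at the start of a loop
#'
#' Sets the first `ceil(window_ms * f_samp / 1000)` samples of the loop to
#' zero; the stimulation artifact coincides with the pulse, so the window is
#' anchored at the loop start.
#'
#' @param loop_samples numeric vector, eEMG samples of one loop (mV).
#' @param window_ms blanking window length in milliseconds (default 10).
#' @param f_samp sampling rate in Hz.
#' @return the loop with the blanking window zeroed; length preserved.
#' @export
blank_artifact <- function(loop_samples, window_ms = 10, f_samp) {
  if (window_ms < 0) stopf("window_ms must be >= 0")
  nz <- as.integer(ceiling(window_ms * f_samp / 1000))
  if (nz >= length(loop_samples)) {
    stopf("blanking window exceeds loop")
  }
  if (nz > 0L) loop_samples[seq_len(nz)] <- 0
  loop_samples
}

#' Zero residual artifact spikes by adjacent-difference thresholding
#'
#' Flags every adjacent sample pair whose absolute difference exceeds
#' `diff_threshold` and zeroes all samples within `template_half_width` of the
#' first sample of the pair. The pass is repeated until a fixed point, so the
#' operation is idempotent.
#'
#' @param loop_samples numeric vector, eEMG samples of one loop (mV).
#' @param diff_threshold positive threshold (mV) on adjacent differences.
#' @param template_half_width half-width of the zeroed window in samples
#'   (default 2).
#' @return the cleaned loop; length preserved.
#' @export
remove_residual_artifacts <- function(loop_samples, diff_threshold,
                                      template_half_width = 2) {
  if (!is.numeric(diff_threshold) || length(diff_threshold) != 1L ||
      !is.finite(diff_threshold) || diff_threshold <= 0) {
    stopf("invalid threshold")
  }
  if (template_half_width < 0) stopf("template_half_width must be >= 0")
  h <- as.integer(template_half_width)
  x <- loop_samples
  n <- length(x)
  if (n < 2L) return(x)
  repeat {
    bad <- which(abs(diff(x)) > diff_threshold)
    if (length(bad) == 0L) break
    zero <- unique(unlist(lapply(bad, function(i) {
      seq.int(max(1L, i - h), min(n, i + h))
    })))
    if (all(x[zero] == 0)) break
    x[zero] <- 0
  }
  x
}

# Robust per-loop default for the residual-artifact threshold. Residual
# artifacts are rare large spikes, so the threshold must clear the steepest
# genuine M-wave slope: a multiple of the 99th percentile of the absolute
# adjacent differences (a median-based default sits below the M-wave slopes
# at realistic noise levels and would zero genuine signal every loop).
# Returns Inf for constant loops so they pass through unchanged.
default_diff_threshold <- function(loop_samples, mult = 3) {
  q <- stats::quantile(abs(diff(loop_samples)), 0.99, names = FALSE,
                       na.rm = TRUE)
  if (!is.finite(q) || q <= 0) return(Inf)
  mult * q
}

#' Convert the dynamometer analog voltage to joint torque
#'
#' The dynamometer exports torque as a linearly scaled analog voltage; the
#' calibrated conversion is 8.64 Nm per volt.
#'
#' @param voltage numeric vector (V).
#' @param gain Nm per volt (default 8.64).
#' @return torque in Nm.
#' @export
scale_torque <- function(voltage, gain = 8.64) {
  if (any(!is.finite(voltage))) stopf("voltage must be finite")
  gain * voltage
}

#' Causal sliding-window smoothing of the MAV series
#'
#' Moving average over the last `round(window_s * f_stim)` loops, using only
#' past loops (shorter prefix at the start) so the real-time causality
#' contract holds.
#'
#' @param u numeric vector, per-loop MAV series.
#' @param window_s window length in seconds (default 0.8).
#' @param f_stim stimulation frequency in Hz.
#' @return smoothed series, same length as `u`.
#' @export
smooth_mav <- function(u, window_s = 0.8, f_stim) {
  if (window_s <= 0) stopf("window_s must be > 0")
  w <- max(1L, round_half_up(window_s * f_stim))
  n <- length(u)
  if (n == 0L) return(u)
  cs <- cumsum(u)
  idx <- seq_len(n)
  lo <- pmax(0L, idx - w)
  (cs - c(0, cs)[lo + 1L]) / (idx - lo)
}

#' Normalize a series by a fixed per-session reference maximum
#'
#' @param x numeric vector.
#' @param reference_max positive reference; the value equal to it maps to 1.
#' @return `x / reference_max`.
#' @export
normalize_series <- function(x, reference_max) {
  if (!is.numeric(reference_max) || length(reference_max) != 1L ||
      !is.finite(reference_max) || reference_max <= 0) {
    stopf("invalid normalization reference")
  }
  x / reference_max
}

#' Extract the per-loop feature series from a raw recording
#'
#' For every stimulation loop: blank the stimulation artifact, zero residual
#' artifact spikes by adjacent-difference thresholding, then take the mean
#' absolute value (MAV) of the cleaned eEMG, and the mean of the torque
#' channel (baseline-corrected and scaled to Nm). The MAV series is finally
#' smoothed with a causal sliding window.
#'
#' @param rec a [raw_recording()].
#' @param ranges loop ranges from [segment_loops()]; computed when `NULL`.
#' @param f_stim stimulation frequency (Hz); derived from pulse gaps when
#'   omitted.
#' @param blank_ms stimulation-artifact blanking window (ms, default 10).
#' @param diff_threshold residual-artifact threshold in mV; when `NULL`
#'   (default) a per-loop robust value is used: `diff_mult` times the 99th
#'   percentile of the absolute adjacent differences, so only spikes well
#'   above the steepest genuine M-wave slope are flagged.
#' @param diff_mult multiplier for the robust default threshold (default 3).
#' @param template_half_width zero-window half-width in samples (default 2).
#' @param smooth_window_s causal MAV smoothing window (s, default 0.8); set
#'   to `NA` to skip smoothing.
#' @param torque_gain Nm per volt (default 8.64).
#' @param baseline_window_s length of the pre-stimulation rest interval whose
#'   mean voltage is subtracted as torque baseline; 0 (default) disables the
#'   correction.
#' @return a `loop_features` data frame with columns `k` (0-based loop index),
#'   `u` (smoothed MAV, mV), `u_raw` (unsmoothed MAV, mV), `tau` (mean torque,
#'   Nm), `pw` (commanded pulse width, us); `f_stim` is stored as attribute.
#' @export
compute_loop_features <- function(rec, ranges = NULL, f_stim = NULL,
                                  blank_ms = 10, diff_threshold = NULL,
                                  diff_mult = 3, template_half_width = 2,
                                  smooth_window_s = 0.8, torque_gain = 8.64,
                                  baseline_window_s = 0) {
  stopifnot(inherits(rec, "raw_recording"))
  if (is.null(f_stim)) {
    if (length(rec$pulse_times) < 2L) {
      stopf("f_stim required for a single-pulse recording")
    }
    f_stim <- 1 / median(diff(rec$pulse_times))
  }
  if (is.null(ranges)) ranges <- segment_loops(rec, f_stim)
  n <- nrow(ranges)
  if (n == 0L) stopf("no stimulation events")

  baseline_v <- 0
  if (baseline_window_s > 0) {
    t0 <- rec$pulse_times[1L]
    i1 <- max(1L, round_half_up((t0 - baseline_window_s) * rec$f_samp) + 1L)
    i2 <- round_half_up(t0 * rec$f_samp)
    if (i2 >= i1) baseline_v <- mean(rec$torque_voltage[i1:i2])
  }

  u_raw <- numeric(n)
  tau <- numeric(n)
  for (k in seq_len(n)) {
    i1 <- ranges[k, "start"] + 1L
    i2 <- ranges[k, "end"]
    if (i2 < i1) stopf("empty loop")
    seg <- rec$emg[i1:i2]
    seg <- blank_artifact(seg, blank_ms, rec$f_samp)
    thr <- if (is.null(diff_threshold)) {
      default_diff_threshold(seg, diff_mult)
    } else {
      diff_threshold
    }
    if (is.finite(thr)) {
      seg <- remove_residual_artifacts(seg, thr, template_half_width)
    }
    u_raw[k] <- mean(abs(seg))
    tau[k] <- scale_torque(mean(rec$torque_voltage[i1:i2]) - baseline_v,
                           torque_gain)
  }
  u <- if (is.na(smooth_window_s)) u_raw else {
    smooth_mav(u_raw, smooth_window_s, f_stim)
  }
  loop_features(k = seq_len(n) - 1L, u = u, u_raw = u_raw, tau = tau,
                pw = rec$pulse_widths, f_stim = f_stim)
}

#' Construct a per-loop feature series
#'
#' @param k 0-based loop indices.
#' @param u smoothed MAV of eEMG per loop (mV), non-negative.
#' @param u_raw unsmoothed MAV per loop (mV); defaults to `u`.
#' @param tau mean torque per loop (Nm).
#' @param pw commanded pulse width per loop (us).
#' @param f_stim stimulation frequency (Hz), in `[1, 1000]`.
#' @return a data frame of class `loop_features`.
#' @export
loop_features <- function(k, u, u_raw = u, tau, pw, f_stim) {
  lens <- c(length(k), length(u), length(u_raw), length(tau), length(pw))
  if (length(unique(lens)) != 1L) {
    stopf("all loop-feature arrays must share one length")
  }
  if (any(u < 0) || any(u_raw < 0)) stopf("MAV must be non-negative")
  if (f_stim < 1 || f_stim > 1000) stopf("f_stim must lie in [1, 1000] Hz")
  out <- data.frame(k = as.integer(k), u = u, u_raw = u_raw, tau = tau,
                    pw = pw)
  attr(out, "f_stim") <- f_stim
  class(out) <- c("loop_features", "data.frame")
  out
}

#' @export
print.loop_features <- function(x, ...) {
  cat(sprintf(
    "<loop_features> %d loops @ %g Hz; MAV %.4g-%.4g mV; torque %.3g-%.3g Nm\n",
    nrow(x), attr(x, "f_stim"), min(x$u), max(x$u), min(x$tau), max(x$tau)
  ))
  invisible(x)
}
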