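# Synthetic FES session generator: per-pulse M-waves with a saturating
# pulse-width recruitment curve, stimulation artifacts, measurement noise,
# and isometric torque produced by second-order low-pass contraction
# dynamics driven by muscle activation. Ground truth (clean per-loop MAV and
# torque) is exposed so estimators can be validated against a known system.

#' Muscle/session simulation parameters
#'
#' @param threshold_pw recruitment threshold pulse width (us): below it no
#'   motor units fire (default 50).
#' @param saturation_pw pulse width at which recruitment saturates (us,
#'   default 350); must exceed `threshold_pw`.
#' @param max_activation activation reached at saturation (dimensionless,
#'   default 1).
#' @param mwave_duration_ms length of the biphasic M-wave template (default
#'   15 ms: long enough to be truncated by an 80 Hz loop, short enough to fit
#'   30-40 Hz loops).
#' @param mwave_latency_ms conduction + synaptic latency between the pulse and
#'   the M-wave onset (default 10 ms, i.e. the M-wave starts where the
#'   stimulation-artifact blanking window ends).
#' @param mwave_amp_mV peak M-wave amplitude per unit activation (default
#'   1.5 mV).
#' @param artifact_amp_mV stimulation artifact amplitude (default 5 mV; the
#'   artifact is a short biphasic rectangular spike at the pulse onset).
#' @param torque_gain_Nm steady-state torque per unit activation (default
#'   15 Nm, an SCI-scale ankle torque).
#' @param fn_hz natural frequency of the second-order contraction dynamics
#'   (default 0.5 Hz, i.e. a torque rise time around a second, typical of
#'   FES-induced isometric contractions).
#' @param damping damping ratio of the contraction dynamics (default 0.9).
#' @param noise_sd_emg per-sample Gaussian noise SD on the eEMG channel (mV,
#'   default 0.02).
#' @param noise_sd_torque per-sample Gaussian noise SD on the torque channel
#'   (Nm, default 0.05).
#' @param fatigue_rate fractional gain decay per minute applied jointly to the
#'   M-wave amplitude and the torque gain (default 0.05: mild early-middle
#'   stage fatigue, no recovery phase).
#' @param seed RNG seed; all simulator randomness flows from it.
#' @return an object of class `muscle_sim_params`.
#' @export
muscle_sim_params <- function(threshold_pw = 50, saturation_pw = 350,
                              max_activation = 1, mwave_duration_ms = 15,
                              mwave_latency_ms = 10, mwave_amp_mV = 1.5,
                              artifact_amp_mV = 5, torque_gain_Nm = 15,
                              fn_hz = 0.5, damping = 0.9,
                              noise_sd_emg = 0.02, noise_sd_torque = 0.05,
                              fatigue_rate = 0.05, seed = NULL) {
  if (!(threshold_pw < saturation_pw)) {
    stopf("invalid simulation config: threshold_pw must be < saturation_pw")
  }
  if (damping <= 0) stopf("invalid simulation config: damping must be > 0")
  if (fn_hz <= 0) stopf("invalid simulation config: fn_hz must be > 0")
  if (noise_sd_emg < 0 || noise_sd_torque < 0) {
    stopf("invalid simulation config: noise SDs must be >= 0")
  }
  if (fatigue_rate < 0) {
    stopf("invalid simulation config: fatigue_rate must be >= 0")
  }
  if (max_activation <= 0) {
    stopf("invalid simulation config: max_activation must be > 0")
  }
  structure(
    list(threshold_pw = threshold_pw, saturation_pw = saturation_pw,
         max_activation = max_activation,
         mwave_duration_ms = mwave_duration_ms,
         mwave_latency_ms = mwave_latency_ms, mwave_amp_mV = mwave_amp_mV,
         artifact_amp_mV = artifact_amp_mV, torque_gain_Nm = torque_gain_Nm,
         fn_hz = fn_hz, damping = damping, noise_sd_emg = noise_sd_emg,
         noise_sd_torque = noise_sd_torque, fatigue_rate = fatigue_rate,
         seed = seed),
    class = "muscle_sim_params"
  )
}

#' Pulse-width recruitment curve
#'
#' Smoothly saturating activation as a function of pulse width: zero below the
#' threshold, a monotone smoothstep rise between threshold and saturation, and
#' `max_activation` beyond saturation.
#'
#' @param pw pulse width in microseconds (vectorized, >= 0).
#' @param params a [muscle_sim_params()].
#' @return activation, dimensionless in `[0, max_activation]`.
#' @export
recruitment_curve <- function(pw, params) {
  stopifnot(inherits(params, "muscle_sim_params"))
  if (any(pw < 0)) stopf("pw must be >= 0")
  s <- (pw - params$threshold_pw) /
    (params$saturation_pw - params$threshold_pw)
  s <- pmin(1, pmax(0, s))
  params$max_activation * (3 * s^2 - 2 * s^3)
}

# One-cycle biphasic M-wave template (damped sine), returned as a sample
# vector for unit activation.
mwave_template <- function(params, f_samp) {
  n <- round_half_up(params$mwave_duration_ms / 1000 * f_samp)
  if (n < 2L) return(numeric(0))
  t <- seq_len(n) - 1L
  dur <- n
  params$mwave_amp_mV * sin(2 * pi * t / dur) * exp(-t / dur)
}

# Biphasic rectangular stimulation artifact (1 ms positive, 1 ms negative).
artifact_template <- function(params, f_samp) {
  n1 <- max(1L, round_half_up(0.001 * f_samp))
  c(rep(params$artifact_amp_mV, n1), rep(-params$artifact_amp_mV, n1))
}

# Exact zero-order-hold discretization of the unit-DC-gain second-order
# system  x'' + 2*zeta*wn*x' + wn^2*x = wn^2*u  at sampling period T.
torque_dynamics_zoh <- function(params, T) {
  wn <- 2 * pi * params$fn_hz
  Ac <- matrix(c(0, -wn^2, 1, -2 * params$damping * wn), 2, 2)
  Bc <- c(0, wn^2)
  Ad <- expm_small(Ac * T)
  Bd <- solve(Ac, (Ad - diag(2)) %*% Bc)
  list(Ad = Ad, Bd = as.numeric(Bd))
}

#' Simulate a full FES session with known ground truth
#'
#' For every stimulation loop of the protocol the simulator inserts a
#' stimulation artifact spike and an activation-scaled biphasic M-wave
#' template (after a physiological latency) into the eEMG channel;
#' overlapping templates superpose, so at high stimulation frequency each
#' loop observes a truncated M-wave. Isometric torque is the response of a
#' second-order low-pass system (discretized by exact zero-order hold at the
#' loop rate) to the activation series, scaled by the torque gain; fatigue
#' decays both the M-wave amplitude and the torque gain exponentially.
#' Gaussian measurement noise is added to both raw channels. The clean
#' (artifact-free, noise-free) per-loop MAV and torque are exposed as ground
#' truth.
#'
#' @param protocol an `fes_protocol` (see [build_sequence()]) giving the
#'   per-loop pulse widths.
#' @param params a [muscle_sim_params()].
#' @param f_samp sampling rate in Hz (default 4096).
#' @return an object of class `fes_session`: list with `recording`
#'   ([raw_recording()]), `truth` (data frame `k`, `t_s`, `pw_us`,
#'   `activation`, `clean_u`, `clean_tau`), `protocol`, `params`, `f_samp`.
#' @export
simulate_session <- function(protocol, params, f_samp = 4096) {
  stopifnot(inherits(protocol, "fes_protocol"))
  stopifnot(inherits(params, "muscle_sim_params"))
  cfg <- attr(protocol, "config")
  f_stim <- cfg$f_stim
  if (nrow(protocol) < 1L) stopf("invalid simulation config: empty protocol")
  if (f_samp < 4 * f_stim) {
    stopf("invalid simulation config: f_samp too low for f_stim")
  }

  t_pulse <- protocol$t_s
  pw <- protocol$pw_us
  n_loops <- length(t_pulse)
  n_samp <- as.integer(ceiling((t_pulse[n_loops] + 1 / f_stim) * f_samp))
  onsets <- round_half_up(t_pulse * f_samp)  # 0-based

  act <- recruitment_curve(pw, params)
  fat <- exp(-params$fatigue_rate * t_pulse / 60)

  # clean eEMG: superposed M-wave templates
  tmpl <- mwave_template(params, f_samp)
  lat <- as.integer(ceiling(params$mwave_latency_ms / 1000 * f_samp))
  clean_emg <- numeric(n_samp)
  nt <- length(tmpl)
  if (nt > 0L) {
    for (k in seq_len(n_loops)) {
      if (pw[k] <= 0 || act[k] <= 0) next
      i0 <- onsets[k] + lat + 1L  # 1-based start
      i1 <- min(n_samp, i0 + nt - 1L)
      if (i0 > n_samp) next
      len <- i1 - i0 + 1L
      clean_emg[i0:i1] <- clean_emg[i0:i1] + act[k] * fat[k] * tmpl[seq_len(len)]
    }
  }

  # artifacts at pulse onset (only when a pulse is actually delivered)
  art <- artifact_template(params, f_samp)
  na <- length(art)
  artifact_sig <- numeric(n_samp)
  for (k in seq_len(n_loops)) {
    if (pw[k] <= 0) next
    i0 <- onsets[k] + 1L
    i1 <- min(n_samp, i0 + na - 1L)
    len <- i1 - i0 + 1L
    artifact_sig[i0:i1] <- artifact_sig[i0:i1] + art[seq_len(len)]
  }

  # torque: ZOH-discretized second-order dynamics at the loop rate
  dyn <- torque_dynamics_zoh(params, 1 / f_stim)
  x <- c(0, 0)
  clean_tau <- numeric(n_loops)
  for (k in seq_len(n_loops)) {
    clean_tau[k] <- params$torque_gain_Nm * fat[k] * x[1]
    x <- dyn$Ad %*% x + dyn$Bd * act[k]
  }

  # raw torque channel: per-loop value held over the loop's samples (V)
  lens <- diff(c(onsets, n_samp))
  tau_raw <- c(rep(0, onsets[1L]), rep(clean_tau, times = lens))
  tau_raw <- tau_raw[seq_len(n_samp)]

  sim <- with_seed(params$seed, {
    list(e = if (params$noise_sd_emg > 0) {
           rnorm(n_samp, 0, params$noise_sd_emg)
         } else numeric(n_samp),
         t = if (params$noise_sd_torque > 0) {
           rnorm(n_samp, 0, params$noise_sd_torque)
         } else numeric(n_samp))
  })

  emg <- clean_emg + artifact_sig + sim$e
  torque_v <- (tau_raw + sim$t) / 8.64

  rec <- raw_recording(emg, torque_v, f_samp, t_pulse, pw,
                       pw_max = cfg$pw_cap)

  # clean per-loop MAV ground truth, via the same segmentation as the pipeline
  ranges <- segment_loops(rec, f_stim)
  clean_u <- vapply(seq_len(n_loops), function(k) {
    mean(abs(clean_emg[(ranges[k, "start"] + 1L):ranges[k, "end"]]))
  }, numeric(1))

  structure(
    list(recording = rec,
         truth = data.frame(k = seq_len(n_loops) - 1L, t_s = t_pulse,
                            pw_us = pw, activation = act,
                            clean_u = clean_u, clean_tau = clean_tau),
         protocol = protocol, params = params, f_samp = f_samp,
         f_stim = f_stim),
    class = "fes_session"
  )
}

#' @export
print.fes_session <- function(x, ...) {
  cat(sprintf(
    "<fes_session> %d loops @ %g Hz (%.1f s), peak clean torque %.2f Nm\n",
    nrow(x$truth), x$f_stim, nrow(x$truth) / x$f_stim, max(x$truth$clean_tau)
  ))
  invisible(x)
}
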