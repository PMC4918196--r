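# Shared fixtures: everything is generated in code at test time.

# Small two-phase session (identification + prediction) for pipeline-level
# tests; f_samp reduced where the spec does not pin it, to keep tests fast.
quick_session_cfg <- function(seed = 1, f_stim = 24, f_samp = 2048,
                              sim_params = NULL, ...) {
  session_config(seed = seed, f_stim = f_stim, f_samp = f_samp,
                 n_cycles_id = 2, n_cycles_pred = 2, id_duration_s = 8,
                 sim_params = sim_params, verbose = FALSE, ...)
}

# Simulate a session exactly as run_session would, but return the raw pieces.
simulate_like_session <- function(cfg) {
  seeds <- festorque:::with_seed(cfg$seed,
                                 sample.int(.Machine$integer.max - 1L, 2L))
  protocol <- festorque:::session_protocol(cfg, seed_pred = seeds[1L])
  sp <- cfg$sim_params
  sp$seed <- seeds[2L]
  simulate_session(protocol, sp, f_samp = cfg$f_samp)
}

# Hand-built raw recording: per-loop constant channels, no artifacts.
flat_recording <- function(emg_loops, tau_v_loops, f_samp = 100,
                           f_stim = 10) {
  n_loop <- as.integer(f_samp / f_stim)
  k <- seq_along(emg_loops) - 1L
  raw_recording(
    emg = rep(emg_loops, each = n_loop),
    torque_voltage = rep(tau_v_loops, each = n_loop),
    f_samp = f_samp,
    pulse_times = k / f_stim,
    pulse_widths = rep(100, length(k))
  )
}

# Stable hand-built PHM parameter set (l = m = n = 2) and its exact
# simulation, matching kf_identify's zero-padded regressor convention.
phm_truth <- function() {
  list(a = c(0.6, -0.08),
       d = matrix(c(0.30, 0.10, 0.20, 0.05), nrow = 2, byrow = TRUE))
}

phm_simulate <- function(u, a, d) {
  l <- length(a); m <- nrow(d); n <- ncol(d)
  N <- length(u)
  y <- numeric(N)
  for (k in seq_len(N)) {
    acc <- 0
    for (i in seq_len(l)) if (k - i >= 1) acc <- acc + a[i] * y[k - i]
    for (i in seq_len(m)) {
      ui <- if (k - i >= 1) u[k - i] else 0
      for (j in seq_len(n)) acc <- acc + d[i, j] * ui^j
    }
    y[k] <- acc
  }
  y
}

# Stable hand-built NARX parameter set (l = m = n = 2).
narx_truth <- function() {
  narx_parameters(v = c(0.50, 0.10),
                  w = matrix(c(0.40, -0.10, 0.15, 0.05), nrow = 2,
                             byrow = TRUE),
                  a = 0.08, b = -0.05)
}

# Fabricated phm_fit wrapper around known parameters (absolute scale).
phm_fit_from <- function(a, d) {
  structure(
    list(a = a, d = d, theta = c(a, as.vector(t(d))),
         orders = c(l = length(a), m = nrow(d), n = ncol(d)),
         lambda = 1, mode = "rls", state = NULL,
         u_scale = 1, tau_scale = 1, y_hat = numeric(0), n = 0L,
         per_loop_time = numeric(0)),
    class = "phm_fit"
  )
}
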