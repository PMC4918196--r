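test_that("recruitment_curve is zero below threshold, saturates, monotone", {
  p <- muscle_sim_params()
  expect_equal(recruitment_curve(0, p), 0)
  expect_equal(recruitment_curve(p$threshold_pw, p), 0)
  expect_equal(recruitment_curve(p$saturation_pw, p), p$max_activation,
               tolerance = 0.01)
  grid <- seq(0, 400, by = 0.5)
  expect_true(all(diff(recruitment_curve(grid, p)) >= 0))
  expect_error(recruitment_curve(-5, p), ">= 0")
})

test_that("muscle_sim_params rejects inconsistent configurations", {
  expect_error(muscle_sim_params(threshold_pw = 400), "invalid simulation")
  expect_error(muscle_sim_params(damping = 0), "invalid simulation")
  expect_error(muscle_sim_params(noise_sd_emg = -1), "invalid simulation")
  expect_error(muscle_sim_params(fatigue_rate = -0.1), "invalid simulation")
})

test_that("zero-PW protocol yields noise-only eEMG and near-zero torque", {
  cfg <- protocol_config(n_cycles = 2, f_stim = 20)
  prot <- build_sequence(cfg)
  prot$pw_us[] <- 0
  p <- muscle_sim_params(seed = 5)
  ses <- simulate_session(prot, p, f_samp = 1024)
  expect_equal(ses$truth$clean_tau, rep(0, nrow(ses$truth)))
  expect_equal(ses$truth$clean_u, rep(0, nrow(ses$truth)))
  n <- length(ses$recording$emg)
  se_e <- p$noise_sd_emg / sqrt(n)
  expect_lt(abs(mean(ses$recording$emg)), 3 * se_e)
  se_t <- p$noise_sd_torque / 8.64 / sqrt(n)
  expect_lt(abs(mean(ses$recording$torque_voltage)), 3 * se_t)
})

test_that("steady-state torque equals torque_gain * activation", {
  # long plateau at saturation, noiseless, no fatigue
  cfg <- protocol_config(n_cycles = 1, plateau_s = 12, rest_s = 0.5,
                         id_range = c(1, 1), f_stim = 20)
  p <- muscle_sim_params(noise_sd_emg = 0, noise_sd_torque = 0,
                         fatigue_rate = 0)
  ses <- simulate_session(build_sequence(cfg), p, f_samp = 1024)
  settle <- ses$truth$t_s > 8 & ses$truth$t_s < 12
  expect_equal(mean(ses$truth$clean_tau[settle]),
               p$torque_gain_Nm * p$max_activation, tolerance = 0.01)
})

test_that("a fixed seed reproduces the session bit for bit", {
  cfg <- quick_session_cfg(seed = 3)
  s1 <- simulate_like_session(cfg)
  s2 <- simulate_like_session(cfg)
  expect_identical(s1$recording$emg, s2$recording$emg)
  expect_identical(s1$recording$torque_voltage, s2$recording$torque_voltage)
  expect_identical(s1$truth, s2$truth)
})

test_that("clean MAV is monotone in PW in the noiseless case", {
  cfg <- protocol_config(n_cycles = 3, f_stim = 20)
  p <- muscle_sim_params(noise_sd_emg = 0, noise_sd_torque = 0,
                         fatigue_rate = 0)
  ses <- simulate_session(build_sequence(cfg), p, f_samp = 2048)
  # average clean MAV per commanded PW level must increase with PW
  lv <- split(ses$truth$clean_u, round(ses$truth$pw_us))
  m <- vapply(lv, mean, numeric(1))
  pw <- as.numeric(names(m))
  # monotone up to the ~1% per-loop length jitter of the segmentation
  expect_true(all(diff(m[order(pw)]) > -0.01 * max(m)))
})

test_that("fatigue decays torque and MAV proportionally across cycles", {
  cfg <- protocol_config(n_cycles = 5, id_range = c(0.8, 0.8), f_stim = 20)
  p <- muscle_sim_params(noise_sd_emg = 0, noise_sd_torque = 0,
                         fatigue_rate = 2)   # strong, to make decay visible
  ses <- simulate_session(build_sequence(cfg), p, f_samp = 1024)
  peak <- vapply(split(ses$truth$clean_tau, ses$protocol$cycle_id), max,
                 numeric(1))
  expect_true(all(diff(peak) < 0))
  peak_u <- vapply(split(ses$truth$clean_u, ses$protocol$cycle_id), max,
                   numeric(1))
  expect_true(all(diff(peak_u) < 0))
  # proportional decay: torque/MAV ratio at cycle peaks stays constant
  ratio <- peak / peak_u
  expect_lt(diff(range(ratio)) / mean(ratio), 0.05)
})

test_that("the M-wave template is truncated by an 80 Hz loop", {
  p <- muscle_sim_params()
  f_samp <- 4096
  tmpl_len <- length(festorque:::mwave_template(p, f_samp))
  lat <- ceiling(p$mwave_latency_ms / 1000 * f_samp)
  expect_gt(lat + tmpl_len, round(f_samp / 80))  # exceeds the 80 Hz loop
  expect_lte(lat + tmpl_len, round(f_samp / 40)) # fits the 40 Hz loop
})

test_that("pipeline MAV reproduces the clean MAV despite artifacts", {
  cfg <- quick_session_cfg(
    seed = 2, f_samp = 2048,
    sim_params = muscle_sim_params(noise_sd_emg = 0, noise_sd_torque = 0)
  )
  ses <- simulate_like_session(cfg)
  f <- compute_loop_features(ses$recording, f_stim = cfg$f_stim,
                             smooth_window_s = NA)
  ref <- ses$truth$clean_u
  big <- ref > 0.01 * max(ref)
  expect_lt(max(abs(f$u_raw[big] - ref[big]) / ref[big]), 0.01)
  expect_lt(max(abs(f$u_raw[!big] - ref[!big])), 0.01 * max(ref))
})

test_that("blanking and thresholding commute when spikes sit in the blank window", {
  cfg <- quick_session_cfg(
    seed = 6, f_samp = 2048,
    sim_params = muscle_sim_params(noise_sd_emg = 0, noise_sd_torque = 0)
  )
  ses <- simulate_like_session(cfg)
  rec <- ses$recording
  ranges <- segment_loops(rec, cfg$f_stim)
  thr <- 1.0
  for (k in unique(round(seq(1, nrow(ranges), length.out = 12)))) {
    seg <- rec$emg[(ranges[k, "start"] + 1L):ranges[k, "end"]]
    a <- remove_residual_artifacts(blank_artifact(seg, 10, rec$f_samp),
                                   thr, 2)
    b <- blank_artifact(remove_residual_artifacts(seg, thr, 2),
                        10, rec$f_samp)
    expect_equal(mean(abs(a)), mean(abs(b)), tolerance = 1e-12)
  }
})
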