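test_that("segment_loops tiles the stimulated span as in the worked examples", {
  # pulses at 0, 0.025, 0.050 s @ 4096 Hz, f_stim 40 -> [0,102) [102,205) [205,307)
  rec <- raw_recording(emg = numeric(320), torque_voltage = numeric(320),
                       f_samp = 4096, pulse_times = c(0, 0.025, 0.050),
                       pulse_widths = c(100, 100, 100))
  r <- segment_loops(rec)
  expect_equal(unname(r[, "start"]), c(0L, 102L, 205L))
  expect_equal(unname(r[, "end"]), c(102L, 205L, 307L))
  expect_setequal(unname(r[, "end"] - r[, "start"]), c(102L, 103L))

  # partition: contiguous, pairwise disjoint
  expect_equal(unname(r[-1L, "start"]), unname(r[-nrow(r), "end"]))

  # single pulse needs f_stim and gets the nominal loop length
  rec1 <- raw_recording(numeric(110), numeric(110), 4096, 0, 100)
  r1 <- segment_loops(rec1, f_stim = 40)
  expect_equal(unname(r1[1L, ]), c(0L, 102L))
  expect_error(segment_loops(rec1), "f_stim required")

  # pulse beyond the recording end
  short <- raw_recording(numeric(100), numeric(100), 4096, 0, 100)
  expect_error(segment_loops(short, f_stim = 40), "truncated")
})

test_that("raw_recording enforces its invariants", {
  expect_error(raw_recording(1:5, 1:4, 100, 0, 10), "equal length")
  expect_error(raw_recording(numeric(50), numeric(50), 100,
                             numeric(0), numeric(0)),
               "no stimulation events")
  expect_error(raw_recording(numeric(50), numeric(50), 100,
                             c(0, 0.2, 0.1), c(1, 1, 1)),
               "strictly increasing")
  expect_error(raw_recording(numeric(500), numeric(500), 100,
                             c(0, 0.1, 0.25), c(1, 1, 1)),
               "1%")
  expect_error(raw_recording(numeric(50), numeric(50), 100, 0, 400,
                             pw_max = 350),
               "pw_max")
})

test_that("blank_artifact zeroes ceil(window_ms * f_samp / 1000) samples", {
  x <- rep(1, 120)
  out <- blank_artifact(x, 10, 4096)
  expect_equal(sum(out == 0), 41L)            # ceil(40.96)
  expect_equal(out[42:120], x[42:120])
  expect_equal(blank_artifact(x, 0, 4096), x)  # 0 ms -> identity
  expect_equal(blank_artifact(numeric(120), 10, 4096), numeric(120))
  expect_error(blank_artifact(rep(1, 30), 10, 4096), "exceeds loop")
})

test_that("remove_residual_artifacts matches the hand-traced rule", {
  x <- c(0, 0.1, 5.0, 0.2, 0)
  expect_equal(remove_residual_artifacts(x, 1.0, 1), rep(0, 5))
  # the last sample is outside every zero zone and survives
  x2 <- c(0, 0.1, 5.0, 0.2, 0.3)
  expect_equal(remove_residual_artifacts(x2, 1.0, 1), c(0, 0, 0, 0, 0.3))
  # threshold above every |diff| -> identity; constant -> identity
  expect_equal(remove_residual_artifacts(x, 10, 1), x)
  expect_equal(remove_residual_artifacts(rep(2, 9), 0.5, 2), rep(2, 9))
  expect_error(remove_residual_artifacts(x, 0, 1), "invalid threshold")
  expect_error(remove_residual_artifacts(x, -1, 1), "invalid threshold")
})

test_that("remove_residual_artifacts is idempotent on random loops", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(80, sd = 0.2)
    x[sample(5:75, 2)] <- rnorm(2, sd = 6)    # injected spikes
    once <- remove_residual_artifacts(x, 1.0, 2)
    expect_identical(remove_residual_artifacts(once, 1.0, 2), once)
  }
})

test_that("scale_torque applies the calibrated 8.64 Nm/V linear map", {
  expect_equal(scale_torque(1.0), 8.64)
  expect_equal(scale_torque(0), 0)
  expect_equal(scale_torque(-0.5), -4.32)
  expect_equal(scale_torque(c(1, 2)), c(8.64, 17.28))
  expect_error(scale_torque(NaN), "finite")
})

test_that("smooth_mav is a causal prefix-clipped moving average", {
  # window 0.8 s at 40 Hz -> 32 loops
  u <- rep(3, 50)
  expect_equal(smooth_mav(u, 0.8, 40), u)     # constant unchanged
  set.seed(4)
  u <- runif(10)
  got <- smooth_mav(u, 3 / 7, 7)              # 3-loop window
  want <- vapply(1:10, function(k) mean(u[max(1, k - 2):k]), numeric(1))
  expect_equal(got, want)
  expect_error(smooth_mav(u, 0, 7), "window_s")
})

test_that("normalize_series divides by a fixed positive reference", {
  expect_equal(normalize_series(1, 2), 0.5)
  expect_equal(normalize_series(2, 2), 1.0)
  expect_error(normalize_series(1:3, 0), "invalid normalization reference")
  expect_error(normalize_series(1:3, -1), "invalid normalization reference")
})

test_that("compute_loop_features extracts MAV and scaled mean torque", {
  # +-1 alternating eEMG -> MAV 1; constant -0.5 -> MAV 0.5 (sign invariant)
  rec <- flat_recording(emg_loops = c(1, -0.5, 0.25),
                        tau_v_loops = c(2, 4, 3))
  rec$emg[1:10] <- rep(c(1, -1), 5)
  f <- compute_loop_features(rec, blank_ms = 0, smooth_window_s = NA,
                             torque_gain = 1)
  expect_equal(f$u_raw, c(1, 0.5, 0.25))
  expect_equal(f$tau, c(2, 4, 3))
  f2 <- compute_loop_features(rec, blank_ms = 0, smooth_window_s = NA)
  expect_equal(f2$tau, 8.64 * c(2, 4, 3))

  # MAV is invariant to a sign flip of the eEMG channel
  rec_flip <- rec
  rec_flip$emg <- -rec_flip$emg
  f3 <- compute_loop_features(rec_flip, blank_ms = 0, smooth_window_s = NA)
  expect_equal(f3$u_raw, f$u_raw)
})

test_that("torque baseline subtraction uses the pre-stimulation rest interval", {
  f_samp <- 100; f_stim <- 10
  n_pre <- 50                                  # 0.5 s of rest before pulse 1
  emg <- numeric(n_pre + 30)
  tv <- c(rep(0.25, n_pre), rep(1.25, 30))     # 0.25 V offset
  rec <- raw_recording(emg, tv, f_samp, pulse_times = 0.5 + (0:2) / f_stim,
                       pulse_widths = rep(100, 3))
  f <- compute_loop_features(rec, blank_ms = 0, smooth_window_s = NA,
                             torque_gain = 1, baseline_window_s = 0.5)
  expect_equal(f$tau, rep(1.0, 3))
})

test_that("loop_features validates shared lengths and non-negative MAV", {
  expect_error(loop_features(0:2, u = c(1, 2), tau = 1:3, pw = 1:3,
                             f_stim = 40),
               "share one length")
  expect_error(loop_features(0:1, u = c(-1, 1), tau = 1:2, pw = 1:2,
                             f_stim = 40),
               "non-negative")
  expect_error(loop_features(0L, u = 1, tau = 1, pw = 1, f_stim = 2000),
               "f_stim")
})
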