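test_that("session_config rejects an identification phase that is too short", {
  expect_error(session_config(id_duration_s = 0.2, f_stim = 24),
               "exceed the parameter count")
  expect_error(session_config(source = "load"), "requires recording_path")
  expect_error(session_config(f_stim = 2000), "f_stim")
})

test_that("run_session is deterministic for a fixed seed", {
  cfg <- quick_session_cfg(seed = 13)
  r1 <- run_session(cfg)
  r2 <- run_session(cfg)
  expect_identical(r1$features$u, r2$features$u)
  for (nm in names(r1$reports)) {
    expect_identical(r1$reports[[nm]]$tau_pred, r2$reports[[nm]]$tau_pred)
    expect_identical(r1$reports[[nm]]$vaf_pct, r2$reports[[nm]]$vaf_pct)
  }
})

test_that("both estimators run on the identical feature series", {
  cfg <- quick_session_cfg(seed = 14)
  r <- run_session(cfg)
  expect_named(r$reports, c("kalman", "narx"))
  expect_identical(r$reports$kalman$tau_meas, r$reports$narx$tau_meas)
  expect_identical(r$reports$kalman$k_id, r$reports$narx$k_id)
})

test_that("no measured torque beyond the boundary influences predictions", {
  cfg <- quick_session_cfg(seed = 15)
  ses <- simulate_like_session(cfg)
  dir_a <- withr::local_tempdir()
  write_recording(ses$recording, file.path(dir_a, "rec.csv"),
                  file.path(dir_a, "pulses.csv"))
  # corrupt the torque channel strictly after the identification boundary
  rec2 <- ses$recording
  cut <- ceiling(cfg$id_duration_s * cfg$f_samp) + as.integer(cfg$f_samp)
  rec2$torque_voltage[cut:length(rec2$torque_voltage)] <-
    rec2$torque_voltage[cut:length(rec2$torque_voltage)] + 3
  write_recording(rec2, file.path(dir_a, "rec2.csv"),
                  file.path(dir_a, "pulses2.csv"))
  mk <- function(rp, pp) {
    session_config(source = "load", recording_path = rp, pulses_path = pp,
                   f_samp = cfg$f_samp, f_stim = cfg$f_stim,
                   id_duration_s = cfg$id_duration_s, verbose = FALSE)
  }
  ra <- run_session(mk(file.path(dir_a, "rec.csv"),
                       file.path(dir_a, "pulses.csv")))
  rb <- run_session(mk(file.path(dir_a, "rec2.csv"),
                       file.path(dir_a, "pulses2.csv")))
  for (nm in names(ra$reports)) {
    expect_identical(ra$reports[[nm]]$tau_pred, rb$reports[[nm]]$tau_pred)
  }
})

test_that("artifact files round-trip losslessly and carry the schema", {
  cfg <- quick_session_cfg(seed = 16)
  dir <- withr::local_tempdir()
  cfg$out_dir <- dir
  r <- run_session(cfg)

  f2 <- read_loop_features(file.path(dir, "features.csv"))
  expect_equal(f2$u, r$features$u)
  expect_equal(f2$tau, r$features$tau)
  expect_equal(attr(f2, "f_stim"), attr(r$features, "f_stim"))

  pred <- read.csv(file.path(dir, "predictions.csv"))
  expect_true(all(c("k", "tau_Nm", "tau_hat_kalman_Nm",
                    "tau_hat_narx_Nm") %in% names(pred)))
  expect_equal(pred$tau_hat_narx_Nm, r$reports$narx$tau_pred)

  rep <- read.csv(file.path(dir, "report.csv"))
  expect_equal(nrow(rep), 2L)
  expect_true(all(c("subject_id", "estimator", "rmse_Nm", "nrmse_pct",
                    "vaf_pct") %in% names(rep)))
  expect_true(file.exists(file.path(dir, "params_kalman.txt")))
  expect_true(file.exists(file.path(dir, "params_narx.txt")))
  expect_true(file.exists(file.path(dir, "session.log")))
})

test_that("recording CSVs round-trip through write/read", {
  cfg <- quick_session_cfg(seed = 17)
  ses <- simulate_like_session(cfg)
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "rec.csv"); pp <- file.path(dir, "pulses.csv")
  write_recording(ses$recording, sp, pp)
  rec2 <- read_recording(sp, pp)
  expect_equal(rec2$emg, ses$recording$emg)
  expect_equal(rec2$torque_voltage, ses$recording$torque_voltage)
  expect_equal(rec2$pulse_times, ses$recording$pulse_times)
  expect_equal(rec2$f_samp, ses$recording$f_samp, tolerance = 1e-9)
})

test_that("malformed feature files fail with a named-column error", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.csv")
  writeLines(c("k,u_mav_mV,tau_Nm", "0,1,2"), p)
  expect_error(read_loop_features(p), "pw_us")
  writeLines(c("1,2,3,4", "0,1,2,3"), p)
  expect_error(read_loop_features(p), "unrecognized file dialect")
})

test_that("the CLI dispatches its subcommands", {
  dir <- withr::local_tempdir()
  expect_output(fes_cli(c("show-config", "--f-stim", "24", "--seed", "5")),
                "f_stim = 24")
  # simulate writes the recording trio
  fes_cli(c("simulate", "--seed", "3", "--f-stim", "20", "--f-samp", "1024",
            "--cycles-id", "1", "--cycles-pred", "1", "--id-duration", "3",
            "--out-dir", dir, "--quiet"))
  expect_true(file.exists(file.path(dir, "recording.csv")))
  expect_true(file.exists(file.path(dir, "pulses.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  # preprocess consumes them
  fes_cli(c("preprocess", "--recording", file.path(dir, "recording.csv"),
            "--pulses", file.path(dir, "pulses.csv"),
            "--f-stim", "20", "--f-samp", "1024",
            "--out-dir", dir, "--quiet"))
  expect_true(file.exists(file.path(dir, "features.csv")))
  # config file + flag override
  cfgf <- file.path(dir, "cfg.txt")
  writeLines(c("f_stim = 24", "seed = 9"), cfgf)
  expect_output(fes_cli(c("show-config", "--config", cfgf)), "f_stim = 24")
  expect_error(fes_cli(c("frobnicate")), "unknown subcommand")
})

test_that("the CLI run subcommand completes a small session end to end", {
  dir <- withr::local_tempdir()
  out <- capture.output(
    res <- fes_cli(c("run", "--seed", "4", "--f-stim", "20",
                     "--f-samp", "1024", "--cycles-id", "2",
                     "--cycles-pred", "1", "--id-duration", "7",
                     "--out-dir", dir, "--quiet"))
  )
  expect_s3_class(res, "session_result")
  expect_true(any(grepl("VAF", out)))
  ev <- capture.output(
    fes_cli(c("evaluate", "--predictions",
              file.path(dir, "predictions.csv")))
  )
  expect_true(any(grepl("VAF", ev)))
})
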