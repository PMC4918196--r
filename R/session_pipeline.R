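# End-to-end session orchestration: simulate or load a recording, extract
# the per-loop features, identify on the first phase, free-run predict on
# the second, evaluate, and write artifacts. Real-time behaviour is emulated
# logically (loop-by-loop causal processing with per-loop timing reported),
# not enforced against wall-clock deadlines.

#' Session configuration
#'
#' Validated bundle of everything [run_session()] needs. The configuration
#' fails fast when the identification phase cannot cover the parameter count
#' of the chosen estimator.
#'
#' @param source `"simulate"` (default) or `"load"`.
#' @param recording_path,pulses_path input CSVs when `source = "load"`.
#' @param f_samp sampling rate (Hz, default 4096).
#' @param f_stim stimulation frequency (Hz; 40 is the able-bodied profile,
#'   30 the SCI profile).
#' @param id_duration_s identification-phase duration (s, default 30): loops
#'   with `t < id_duration_s` train the estimators, the rest are predicted.
#' @param estimator `"kalman"`, `"narx"` or `"both"` (default).
#' @param orders model orders `c(l, m, n)` shared by both estimators
#'   (default `c(2, 2, 2)`).
#' @param lambda Kalman forgetting factor (default 0.95).
#' @param kalman_mode `"ekf"` (default) or `"rls"`.
#' @param normalize_kalman normalize the Kalman path to `[0, 1]` by
#'   identification-phase maxima (default `TRUE`).
#' @param n_cycles_id,n_cycles_pred trapezoidal cycles in each phase
#'   (defaults 8 and 10; a 4 s cycle makes the identification sequence span
#'   the 30 s boundary).
#' @param pw_max maximum pulse width (us, default 350).
#' @param sim_params a [muscle_sim_params()] for `source = "simulate"`
#'   (default constructed with package defaults).
#' @param smooth_window_s causal MAV smoothing window (s, default 0.8).
#' @param blank_ms artifact blanking window (ms, default 10).
#' @param baseline_window_s pre-stimulation torque baseline interval (s,
#'   default 0).
#' @param seed master seed; protocol randomness and simulator noise are
#'   derived from it.
#' @param out_dir when non-`NULL`, artifacts (features, parameter dumps,
#'   predictions, report, log) are written there.
#' @param verbose emit progress messages to stderr (default `TRUE`); the log
#'   file under `out_dir` is written either way.
#' @return an object of class `session_config`.
#' @export
session_config <- function(source = c("simulate", "load"),
                           recording_path = NULL, pulses_path = NULL,
                           f_samp = 4096, f_stim = 40, id_duration_s = 30,
                           estimator = c("both", "kalman", "narx"),
                           orders = c(2, 2, 2), lambda = 0.95,
                           kalman_mode = c("ekf", "rls"),
                           normalize_kalman = TRUE,
                           n_cycles_id = 8, n_cycles_pred = 10,
                           pw_max = 350, sim_params = NULL,
                           smooth_window_s = 0.8, blank_ms = 10,
                           baseline_window_s = 0, seed = 1,
                           out_dir = NULL, verbose = TRUE) {
  source <- match.arg(source)
  estimator <- match.arg(estimator)
  kalman_mode <- match.arg(kalman_mode)
  orders <- phm_orders(orders)
  if (f_stim < 1 || f_stim > 1000) stopf("f_stim must lie in [1, 1000] Hz")
  n_par <- orders[["l"]] + orders[["m"]] * orders[["n"]] + 2L
  if (id_duration_s * f_stim <= n_par) {
    stopf("id_duration_s * f_stim (%g) must exceed the parameter count (%d)",
          id_duration_s * f_stim, n_par)
  }
  if (source == "load" &&
      (is.null(recording_path) || is.null(pulses_path))) {
    stopf("source = 'load' requires recording_path and pulses_path")
  }
  if (is.null(sim_params)) sim_params <- muscle_sim_params()
  structure(
    list(source = source, recording_path = recording_path,
         pulses_path = pulses_path, f_samp = f_samp, f_stim = f_stim,
         id_duration_s = id_duration_s, estimator = estimator,
         orders = orders, lambda = lambda, kalman_mode = kalman_mode,
         normalize_kalman = normalize_kalman,
         n_cycles_id = as.integer(n_cycles_id),
         n_cycles_pred = as.integer(n_cycles_pred), pw_max = pw_max,
         sim_params = sim_params, smooth_window_s = smooth_window_s,
         blank_ms = blank_ms, baseline_window_s = baseline_window_s,
         seed = seed, out_dir = out_dir, verbose = isTRUE(verbose)),
    class = "session_config"
  )
}

# Build the two-phase session protocol for a config.
session_protocol <- function(cfg, seed_pred = NULL) {
  id_cfg <- protocol_config(f_stim = cfg$f_stim, pw_max = cfg$pw_max,
                            n_cycles = cfg$n_cycles_id,
                            phase = "identification")
  pr_cfg <- protocol_config(f_stim = cfg$f_stim, pw_max = cfg$pw_max,
                            n_cycles = cfg$n_cycles_pred,
                            phase = "prediction", seed = seed_pred)
  concat_protocols(build_sequence(id_cfg), build_sequence(pr_cfg))
}

session_log <- function(lines, out_dir, verbose = TRUE) {
  if (verbose) for (ln in lines) message(ln)
  if (!is.null(out_dir)) {
    cat(lines, file = file.path(out_dir, "session.log"), sep = "\n",
        append = TRUE)
  }
}

#' Run a full identification + prediction session
#'
#' Simulates (or loads) a recording, extracts the per-loop feature series,
#' identifies the configured estimator(s) on loops with `t < id_duration_s`,
#' free-run predicts torque on all remaining loops from the MAV of eEMG
#' alone, and evaluates RMSE / NRMSE / VAF on the prediction phase. No
#' measured torque beyond the identification boundary reaches any predictor.
#'
#' @param cfg a [session_config()].
#' @return an object of class `session_result`: list with `features`
#'   (the [loop_features()] series), `k_id` (last identified loop, 0-based),
#'   `reports` (named list of [prediction_report()]s), `fits` (named list of
#'   fitted estimators), and `session` (the simulated `fes_session`, when
#'   simulated).
#' @export
run_session <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log <- function(fmt, ...) {
    session_log(sprintf(fmt, ...), out_dir, cfg$verbose)
  }

  session <- NULL
  if (cfg$source == "simulate") {
    seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 2L))
    protocol <- session_protocol(cfg, seed_pred = seeds[1L])
    sp <- cfg$sim_params
    sp$seed <- seeds[2L]
    session <- simulate_session(protocol, sp, f_samp = cfg$f_samp)
    rec <- session$recording
    log("simulated session: %d loops @ %g Hz (seed %s)",
        nrow(session$truth), cfg$f_stim, format(cfg$seed))
  } else {
    rec <- read_recording(cfg$recording_path, cfg$pulses_path,
                          f_samp = cfg$f_samp, pw_max = cfg$pw_max)
    log("loaded recording: %d samples, %d pulses", length(rec$emg),
        length(rec$pulse_times))
  }

  features <- compute_loop_features(
    rec, f_stim = cfg$f_stim, blank_ms = cfg$blank_ms,
    smooth_window_s = cfg$smooth_window_s, torque_gain = 8.64,
    baseline_window_s = cfg$baseline_window_s
  )
  n <- nrow(features)
  t_loop <- features$k / cfg$f_stim
  id_idx <- which(t_loop < cfg$id_duration_s)
  if (length(id_idx) < 1L || length(id_idx) >= n) {
    stopf("identification boundary leaves an empty phase")
  }
  k_id <- max(id_idx) - 1L                 # 0-based boundary loop
  pred_idx <- seq.int(max(id_idx) + 1L, n)
  log("identification: %d loops; prediction: %d loops",
      length(id_idx), length(pred_idx))

  u_id <- features$u[id_idx]
  tau_id <- features$tau[id_idx]
  u_pred <- features$u[pred_idx]
  tau_pred_meas <- features$tau[pred_idx]

  run_est <- if (cfg$estimator == "both") c("kalman", "narx") else {
    cfg$estimator
  }
  fits <- list()
  reports <- list()

  if ("kalman" %in% run_est) {
    fit <- kf_identify(u_id, tau_id, orders = cfg$orders,
                       lambda = cfg$lambda, mode = cfg$kalman_mode,
                       normalize = cfg$normalize_kalman)
    slow <- which(fit$per_loop_time > 1 / cfg$f_stim)
    if (length(slow)) {
      log("warning: %d kalman loops exceeded the %g ms loop budget",
          length(slow), 1000 / cfg$f_stim)
    }
    l <- cfg$orders[["l"]]; m <- cfg$orders[["m"]]
    pred <- kf_free_run_predict(
      u_pred, fit,
      y_init = tail(tau_id, l), u_hist = tail(u_id, m)
    )
    fits$kalman <- fit
    reports$kalman <- prediction_report(tau_pred_meas, pred, k_id,
                                        "kalman", fit$per_loop_time)
  }
  if ("narx" %in% run_est) {
    t0 <- proc.time()[[3L]]
    design <- build_design_matrix(u_id, tau_id, cfg$orders)
    fit <- identify_narx(design)
    t_ident <- proc.time()[[3L]] - t0
    l <- cfg$orders[["l"]]; m <- cfg$orders[["m"]]
    t0 <- proc.time()[[3L]]
    pred <- narx_free_run_predict(
      u_pred, fit,
      tau_init = tail(tau_id, l), u_hist = tail(u_id, m)
    )
    t_pred <- (proc.time()[[3L]] - t0) / length(pred)
    if (t_ident > 1 / cfg$f_stim) {
      log("warning: narx one-shot identification took %.1f ms (> loop budget)",
          1000 * t_ident)
    }
    fits$narx <- fit
    reports$narx <- prediction_report(tau_pred_meas, pred, k_id, "narx",
                                      rep(t_pred, length(pred)))
  }

  for (r in reports) {
    log("%s: RMSE %.4g Nm, NRMSE %.4g %%, VAF %.4g %%",
        r$estimator, r$rmse, r$nrmse_pct, r$vaf_pct)
  }

  if (!is.null(out_dir)) {
    write_loop_features(features, file.path(out_dir, "features.csv"))
    for (nm in names(fits)) {
      write_params(fits[[nm]], file.path(out_dir, paste0("params_", nm, ".txt")))
    }
    pred_df <- data.frame(k = features$k[pred_idx],
                          tau_Nm = tau_pred_meas)
    for (nm in names(reports)) {
      pred_df[[paste0("tau_hat_", nm, "_Nm")]] <- reports[[nm]]$tau_pred
    }
    write_csv_precise(pred_df, file.path(out_dir, "predictions.csv"))
    write_report(reports, file.path(out_dir, "report.csv"),
                 subject_id = sprintf("seed%s", format(cfg$seed)))
    if (!is.null(session)) {
      write_ground_truth(session, file.path(out_dir, "ground_truth.csv"))
    }
    cat(sprintf("seed = %s\n", format(cfg$seed)),
        file = file.path(out_dir, "seed.txt"))
  }

  structure(
    list(features = features, k_id = k_id, reports = reports, fits = fits,
         session = session, config = cfg),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d loops, identification up to k=%d\n",
              nrow(x$features), x$k_id))
  for (r in x$reports) {
    cat(sprintf("  %-7s RMSE %.4g Nm | NRMSE %.4g %% | VAF %.4g %%\n",
                r$estimator, r$rmse, r$nrmse_pct, r$vaf_pct))
  }
  invisible(x)
}
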