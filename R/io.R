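# Delimited-text dialects for recordings, pulse schedules, loop features,
# protocols, parameter dumps and reports. All writers emit a header row and
# full double precision so a write/read round trip is lossless.

fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = TRUE),
         character(1))
}

write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

check_columns <- function(df, cols, path) {
  for (cc in cols) {
    if (!cc %in% names(df)) {
      stopf("format error in '%s': missing column '%s'", path, cc)
    }
  }
}

read_csv_headered <- function(path, required) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, ",", fixed = TRUE)[[1L]]
  if (suppressWarnings(!anyNA(as.numeric(fields)))) {
    stopf("unrecognized file dialect in '%s': missing header", path)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, required, path)
  df
}

#' Write a raw recording to its two-file CSV dialect
#'
#' Signals file columns: `time_s`, `emg_mV`, `torque_V`; pulse file columns:
#' `pulse_time_s`, `pw_us`. Both carry a mandatory header row.
#'
#' @param rec a [raw_recording()].
#' @param signals_path,pulses_path output CSV paths.
#' @return `rec`, invisibly.
#' @export
write_recording <- function(rec, signals_path, pulses_path) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- length(rec$emg)
  write_csv_precise(
    data.frame(time_s = (seq_len(n) - 1L) / rec$f_samp,
               emg_mV = rec$emg, torque_V = rec$torque_voltage),
    signals_path
  )
  write_csv_precise(
    data.frame(pulse_time_s = rec$pulse_times, pw_us = rec$pulse_widths),
    pulses_path
  )
  invisible(rec)
}

#' Read a raw recording from its two-file CSV dialect
#'
#' @param signals_path,pulses_path CSV paths (see [write_recording()]).
#' @param f_samp sampling rate; inferred from the time column when `NULL`.
#' @param pw_max stimulator limit passed through to [raw_recording()].
#' @return a [raw_recording()].
#' @export
read_recording <- function(signals_path, pulses_path, f_samp = NULL,
                           pw_max = 350) {
  sig <- read_csv_headered(signals_path, c("time_s", "emg_mV", "torque_V"))
  pul <- read_csv_headered(pulses_path, c("pulse_time_s", "pw_us"))
  if (is.null(f_samp)) {
    f_samp <- 1 / median(diff(sig$time_s))
  }
  raw_recording(sig$emg_mV, sig$torque_V, f_samp, pul$pulse_time_s,
                pul$pw_us, pw_max = pw_max)
}

#' Write a loop feature series to CSV
#'
#' Columns: `k`, `u_mav_mV`, `tau_Nm`, `pw_us`, plus `u_raw_mV`.
#'
#' @param features a [loop_features()] object.
#' @param path output CSV path.
#' @return `features`, invisibly.
#' @export
write_loop_features <- function(features, path) {
  stopifnot(inherits(features, "loop_features"))
  write_csv_precise(
    data.frame(k = features$k, u_mav_mV = features$u,
               tau_Nm = features$tau, pw_us = features$pw,
               u_raw_mV = features$u_raw,
               f_stim_hz = attr(features, "f_stim")),
    path
  )
  invisible(features)
}

#' Read a loop feature series from CSV
#'
#' Requires columns `k`, `u_mav_mV`, `tau_Nm`, `pw_us`; unknown columns are
#' preserved as attribute `extra`.
#'
#' @param path CSV path.
#' @param f_stim stimulation frequency; read from an `f_stim_hz` column when
#'   present.
#' @return a [loop_features()] object.
#' @export
read_loop_features <- function(path, f_stim = NULL) {
  df <- read_csv_headered(path, c("k", "u_mav_mV", "tau_Nm", "pw_us"))
  if (is.null(f_stim)) {
    if ("f_stim_hz" %in% names(df)) {
      f_stim <- df$f_stim_hz[1L]
    } else {
      stopf("format error in '%s': missing column 'f_stim_hz' (or pass f_stim)",
            path)
    }
  }
  u_raw <- if ("u_raw_mV" %in% names(df)) df$u_raw_mV else df$u_mav_mV
  out <- loop_features(df$k, df$u_mav_mV, u_raw, df$tau_Nm, df$pw_us, f_stim)
  known <- c("k", "u_mav_mV", "tau_Nm", "pw_us", "u_raw_mV", "f_stim_hz")
  extra <- setdiff(names(df), known)
  if (length(extra)) attr(out, "extra") <- df[extra]
  out
}

#' Write an estimator parameter dump as key-value text
#'
#' @param fit a `phm_fit` or `narx_fit`.
#' @param path output path.
#' @return `fit`, invisibly.
#' @export
write_params <- function(fit, path) {
  kv <- function(key, val) sprintf("%s = %s", key,
                                   paste(fmt_num(val), collapse = " "))
  lines <- c(
    sprintf("model = %s", if (inherits(fit, "phm_fit")) "phm" else "narx"),
    sprintf("orders = %d %d %d", fit$orders[["l"]], fit$orders[["m"]],
            fit$orders[["n"]])
  )
  if (inherits(fit, "phm_fit")) {
    lines <- c(lines,
               kv("lambda", fit$lambda),
               sprintf("mode = %s", fit$mode),
               kv("a", fit$a),
               kv("d", as.vector(t(fit$d))),
               kv("u_scale", fit$u_scale),
               kv("tau_scale", fit$tau_scale),
               kv("P_diag", diag(fit$state$P)))
  } else if (inherits(fit, "narx_fit")) {
    lines <- c(lines,
               sprintf("k_id = %s", fit$k_id),
               kv("v", fit$v),
               kv("w", as.vector(t(fit$w))),
               kv("a", fit$a),
               kv("b", fit$b))
  } else {
    stopf("unsupported fit object")
  }
  writeLines(lines, path)
  invisible(fit)
}

#' Write prediction report rows as CSV
#'
#' Columns mirror a per-subject results table: `subject_id`, `estimator`,
#' `rmse_Nm`, `nrmse_pct`, `vaf_pct`.
#'
#' @param reports a `prediction_report` or list of them.
#' @param path output CSV path.
#' @param subject_id label for the subject/session column.
#' @return the report data frame, invisibly.
#' @export
write_report <- function(reports, path, subject_id = "sim") {
  if (inherits(reports, "prediction_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(subject_id = subject_id, estimator = r$estimator,
               rmse_Nm = r$rmse, nrmse_pct = r$nrmse_pct,
               vaf_pct = r$vaf_pct, stringsAsFactors = FALSE)
  }))
  write_csv_precise(df, path)
  invisible(df)
}

#' Write the simulator ground truth to CSV
#'
#' Columns: `k`, `clean_u`, `clean_tau` (plus `t_s`, `pw_us`, `activation`).
#'
#' @param session an `fes_session` from [simulate_session()].
#' @param path output CSV path.
#' @return the truth data frame, invisibly.
#' @export
write_ground_truth <- function(session, path) {
  stopifnot(inherits(session, "fes_session"))
  write_csv_precise(session$truth, path)
  invisible(session$truth)
}
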