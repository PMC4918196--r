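# Prediction-quality measures: RMSE, NRMSE (normalized by the measured
# peak-to-peak range) and VAF (variance accounted for).

#' Evaluate a torque prediction against measurements
#'
#' * `rmse = sqrt(mean((tau - tau_hat)^2))` (Nm)
#' * `nrmse = 100 * rmse / (max(tau) - min(tau))` (%% of the measured
#'   peak-to-peak range; the normalization convention is a package choice —
#'   range, mean and max conventions all circulate)
#' * `vaf = 100 * (1 - var(tau - tau_hat) / var(tau))` (%%), population
#'   (1/N) variances; VAF is not clipped and can be negative (worse than the
#'   mean predictor).
#'
#' @param tau_meas measured torque series (Nm).
#' @param tau_pred predicted torque series, same length.
#' @return list of class `prediction_metrics` with `rmse`, `nrmse_pct`,
#'   `vaf_pct`.
#' @export
evaluate_prediction <- function(tau_meas, tau_pred) {
  tau_meas <- as.numeric(tau_meas)
  tau_pred <- as.numeric(tau_pred)
  if (length(tau_meas) == 0L || length(tau_meas) != length(tau_pred)) {
    stopf("series must be non-empty and of equal length")
  }
  rng <- max(tau_meas) - min(tau_meas)
  if (rng <= 0) stopf("NRMSE undefined: zero measured range")
  v <- var_pop(tau_meas)
  if (v <= 0) stopf("VAF undefined: zero measured variance")
  err <- tau_meas - tau_pred
  rmse <- sqrt(mean(err^2))
  structure(
    list(rmse = rmse,
         nrmse_pct = 100 * rmse / rng,
         vaf_pct = 100 * (1 - var_pop(err) / v)),
    class = "prediction_metrics"
  )
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.4g Nm | NRMSE %.4g %% | VAF %.4g %%\n",
              x$rmse, x$nrmse_pct, x$vaf_pct))
  invisible(x)
}

#' Assemble a prediction report for one estimator
#'
#' @param tau_meas,tau_pred measured and predicted torque over the prediction
#'   phase (`k > k_id`).
#' @param k_id identification boundary (last identified loop, 0-based).
#' @param estimator label, e.g. `"kalman"` or `"narx"`.
#' @param per_loop_time per-loop compute times in seconds (optional).
#' @return object of class `prediction_report`.
#' @export
prediction_report <- function(tau_meas, tau_pred, k_id, estimator,
                              per_loop_time = numeric(0)) {
  m <- evaluate_prediction(tau_meas, tau_pred)
  structure(
    list(estimator = estimator, k_id = as.integer(k_id),
         tau_meas = tau_meas, tau_pred = tau_pred,
         rmse = m$rmse, nrmse_pct = m$nrmse_pct, vaf_pct = m$vaf_pct,
         per_loop_time = per_loop_time),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "<prediction_report> %s | %d prediction loops (k_id=%d)\n  ",
    x$estimator, length(x$tau_meas), x$k_id
  ))
  print(structure(list(rmse = x$rmse, nrmse_pct = x$nrmse_pct,
                       vaf_pct = x$vaf_pct),
                  class = "prediction_metrics"))
  invisible(x)
}
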