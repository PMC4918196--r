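# Recursive forgetting-factor Kalman estimation of a polynomial Hammerstein
# model (PHM) mapping the per-loop MAV of evoked EMG, u(k), to joint torque,
# y(k):
#
#   y(k) = sum_{i=1..l} a_i y(k-i) + sum_{i=1..m} sum_{j=1..n} d_ij u^j(k-i)
#
# The products b_i * c_j of the static polynomial and the linear block are
# not separately identifiable, so the estimator works with the coupled
# coefficients d_ij = b_i c_j directly. Two formulations are provided:
#   - "ekf": joint state + parameter extended Kalman filter whose first state
#     component is the model output (the observer reading, y_hat = x_hat_1);
#   - "rls": linear-in-parameters reduction (regressors built from measured
#     outputs), equivalent to recursive least squares and, at lambda = 1 with
#     a diffuse prior, to batch least squares.

phm_orders <- function(orders) {
  orders <- as.integer(orders)
  if (length(orders) != 3L || any(orders < 1L)) {
    stopf("orders must be three integers >= 1 (l, m, n)")
  }
  names(orders) <- c("l", "m", "n")
  orders
}

#' Polynomial input basis
#'
#' The static nonlinearity of the Hammerstein model:
#' `Phi(u) = [u, u^2, ..., u^n]` (no constant term).
#'
#' @param u scalar input.
#' @param n polynomial degree, >= 1.
#' @return numeric vector of length `n`.
#' @export
poly_basis <- function(u, n) {
  if (n < 1) stopf("polynomial degree must be >= 1")
  u^seq_len(n)
}

# Regressor phi(k) = [y(k-1..k-l); u(k-1)^1..n; ...; u(k-m)^1..n].
# y_lags and u_lags are most-recent-first, zero-padded.
phm_regressor <- function(y_lags, u_lags, n) {
  c(y_lags, unlist(lapply(u_lags, poly_basis, n = n)))
}

#' Initialize the recursive Kalman estimator state
#'
#' @param orders integer vector `c(l, m, n)`: output lags, input lags,
#'   polynomial degree (default `c(2, 2, 2)`).
#' @param lambda forgetting factor in `[0.9, 1]` (default 0.95).
#' @param p0 diffuse prior covariance scale, `P0 = p0 * I` (default 1e3).
#' @param y0 initial output state (typically the first measured torque,
#'   normalized scale); ignored in `"rls"` mode.
#' @param mode `"ekf"` (joint state + parameter filter, default) or `"rls"`
#'   (linear-in-parameters).
#' @param p_cap covariance limitation bound (default 1e6): eigenvalues of
#'   `P` are clipped to `[0, p_cap]` after every update. With `lambda < 1`
#'   the covariance of directions that stay unexcited for long rest periods
#'   grows like `lambda^-k` (estimator wind-up); the cap is the standard
#'   safeguard and leaves well-excited directions untouched.
#' @return an object of class `kalman_state` with fields `x` (augmented
#'   state: output state followed by the parameter vector in `"ekf"` mode;
#'   parameters only in `"rls"` mode), `P` (covariance), `lambda`, `orders`,
#'   `mode`.
#' @export
kf_init <- function(orders = c(2, 2, 2), lambda = 0.95, p0 = 1e3, y0 = 0,
                    mode = c("ekf", "rls"), p_cap = 1e6) {
  orders <- phm_orders(orders)
  mode <- match.arg(mode)
  if (lambda < 0.9 || lambda > 1) {
    stopf("forgetting factor lambda must lie in [0.9, 1]")
  }
  p <- orders[["l"]] + orders[["m"]] * orders[["n"]]
  dim_x <- if (mode == "ekf") 1L + p else p
  x <- numeric(dim_x)
  if (mode == "ekf") x[1L] <- y0
  structure(
    list(x = x, P = diag(p0, dim_x), lambda = lambda, orders = orders,
         mode = mode, n_par = p, p_cap = p_cap),
    class = "kalman_state"
  )
}

#' A priori (prediction) phase of the recursive Kalman estimator
#'
#' Propagates the output component through the Hammerstein recursion with the
#' current parameter estimates and the parameter components as a random walk;
#' the covariance is inflated by the forgetting factor:
#' `P_hat = A P A^T / lambda`, with `A` the Jacobian of the state transition
#' at the current estimate.
#'
#' @param state a `kalman_state`.
#' @param u_lags input history `u(k-1), ..., u(k-m)` (most recent first;
#'   zero-padded before the series start).
#' @param y_lags output history `y(k-1), ..., y(k-l)` (most recent first). In
#'   `"ekf"` mode the lag-1 entry is taken from the state itself
#'   (`x[1]`), so `y_lags[1]` is ignored; in `"rls"` mode these are measured
#'   outputs.
#' @return list with `x_hat`, `P_hat`, `y_hat`, and the observation row `H`.
#' @export
kf_priori <- function(state, u_lags, y_lags) {
  stopifnot(inherits(state, "kalman_state"))
  l <- state$orders[["l"]]
  m <- state$orders[["m"]]
  n <- state$orders[["n"]]
  p <- state$n_par
  u_lags <- c(u_lags, numeric(m))[seq_len(m)]
  y_lags <- c(y_lags, numeric(l))[seq_len(l)]
  if (any(!is.finite(state$x))) stopf("estimator diverged")

  if (state$mode == "ekf") {
    theta <- state$x[-1L]
    y_lags[1L] <- state$x[1L]
    phi <- phm_regressor(y_lags, u_lags, n)
    y_hat <- sum(theta * phi)
    A <- diag(1, 1L + p)
    A[1L, 1L] <- theta[1L]            # d y_hat / d x1 = a_1
    A[1L, 1L + seq_len(p)] <- phi     # d y_hat / d theta
    x_hat <- c(y_hat, theta)
    H <- c(1, numeric(p))
  } else {
    theta <- state$x
    phi <- phm_regressor(y_lags, u_lags, n)
    y_hat <- sum(theta * phi)
    A <- diag(1, p)
    x_hat <- theta
    H <- phi
  }
  P_hat <- A %*% state$P %*% t(A) / state$lambda
  if (!is.finite(y_hat)) stopf("estimator diverged")
  list(x_hat = x_hat, P_hat = P_hat, y_hat = y_hat, H = H)
}

#' A posteriori (update) phase of the recursive Kalman estimator
#'
#' Standard innovation update with the forgetting factor playing the role of
#' the measurement covariance: `S = H P_hat H^T + lambda`,
#' `K = P_hat H^T / S`, `x <- x_hat + K (y - y_hat)`,
#' `P <- (I - K H) P_hat` (symmetrized).
#'
#' @param state a `kalman_state` (for dimensions and `lambda`).
#' @param priori output of [kf_priori()] for this loop.
#' @param y_meas measured output for this loop.
#' @return the updated `kalman_state`.
#' @export
kf_posteriori <- function(state, priori, y_meas) {
  stopifnot(inherits(state, "kalman_state"))
  H <- priori$H
  P_hat <- priori$P_hat
  S <- as.numeric(H %*% P_hat %*% H) + state$lambda
  if (!is.finite(S) || S <= .Machine$double.eps) {
    stopf("singular innovation covariance")
  }
  K <- as.numeric(P_hat %*% H) / S
  state$x <- priori$x_hat + K * (y_meas - priori$y_hat)
  # Joseph-form update: algebraically (I - K H) P_hat for the optimal gain,
  # but keeps P symmetric positive semi-definite under round-off
  IKH <- diag(length(K)) - outer(K, H)
  P <- IKH %*% P_hat %*% t(IKH) + state$lambda * outer(K, K)
  P <- (P + t(P)) / 2
  # covariance limitation: keep P positive semi-definite and bounded
  p_cap <- if (is.null(state$p_cap)) Inf else state$p_cap
  if (max(abs(P)) > p_cap || min(diag(P)) < 0) {
    e <- eigen(P, symmetric = TRUE)
    lam <- pmin(pmax(e$values, 0), p_cap)
    P <- e$vectors %*% (lam * t(e$vectors))
    P <- (P + t(P)) / 2
  }
  state$P <- P
  state
}

# Split the parameter vector into AR coefficients and the d matrix.
phm_split_theta <- function(theta, orders) {
  l <- orders[["l"]]; m <- orders[["m"]]; n <- orders[["n"]]
  list(a = theta[seq_len(l)],
       d = matrix(theta[l + seq_len(m * n)], nrow = m, ncol = n,
                  byrow = TRUE))
}

#' Identify the polynomial Hammerstein model online
#'
#' Runs the a priori / a posteriori recursion over the identification phase,
#' one loop at a time (strictly causal, constant per-loop cost). Inputs and
#' outputs are normalized to `[0, 1]` by their series maxima before
#' identification (the Kalman path requires adequate normalization); the
#' scales are stored so predictions can be reported on the absolute scale.
#'
#' @param u MAV series (mV), identification phase.
#' @param tau torque series (Nm), identification phase; same length as `u`.
#' @param orders `c(l, m, n)` model orders (default `c(2, 2, 2)`).
#' @param lambda forgetting factor in `[0.9, 1]` (default 0.95).
#' @param p0 diffuse prior scale (default 1e3).
#' @param mode `"ekf"` (default) or `"rls"`.
#' @param normalize normalize `u` and `tau` to `[0, 1]` by their maxima
#'   (default `TRUE`).
#' @param p_cap covariance limitation bound, see [kf_init()] (default 1e6).
#' @param divergence_bound error out when the state norm exceeds this bound
#'   (default 1e6).
#' @return an object of class `phm_fit`: parameters `a` (length `l`) and `d`
#'   (`m x n` matrix of coupled coefficients), the final `kalman_state`,
#'   per-loop one-step predictions `y_hat` (absolute scale), normalization
#'   scales, and per-loop compute times.
#' @export
kf_identify <- function(u, tau, orders = c(2, 2, 2), lambda = 0.95,
                        p0 = 1e3, mode = c("ekf", "rls"), normalize = TRUE,
                        p_cap = 1e6, divergence_bound = 1e6) {
  mode <- match.arg(mode)
  orders <- phm_orders(orders)
  u <- as.numeric(u); tau <- as.numeric(tau)
  if (length(u) != length(tau)) stopf("u and tau must have equal length")
  N <- length(u)
  p <- orders[["l"]] + orders[["m"]] * orders[["n"]]
  if (N <= p) stopf("series length must exceed the parameter count (%d)", p)

  u_scale <- if (normalize && max(u) > 0) max(u) else 1
  tau_scale <- if (normalize && max(tau) > 0) max(tau) else 1
  un <- u / u_scale
  yn <- tau / tau_scale

  l <- orders[["l"]]; m <- orders[["m"]]
  state <- kf_init(orders, lambda, p0, y0 = yn[1L], mode = mode,
                   p_cap = p_cap)
  y_hat <- numeric(N)
  y_post <- numeric(N)   # a posteriori output states (ekf) / measured (rls)
  times <- numeric(N)

  lag_of <- function(series, k, i) if (k - i >= 1L) series[k - i] else 0
  for (k in seq_len(N)) {
    t0 <- proc.time()[[3L]]
    u_lags <- vapply(seq_len(m), function(i) lag_of(un, k, i), numeric(1))
    y_src <- if (mode == "ekf") y_post else yn
    y_lags <- vapply(seq_len(l), function(i) lag_of(y_src, k, i), numeric(1))
    pri <- kf_priori(state, u_lags, y_lags)
    y_hat[k] <- pri$y_hat
    state <- kf_posteriori(state, pri, yn[k])
    y_post[k] <- if (mode == "ekf") state$x[1L] else yn[k]
    if (sqrt(sum(state$x^2)) > divergence_bound) {
      stopf("identification failed: state norm exceeded %g at loop %d",
            divergence_bound, k)
    }
    times[k] <- proc.time()[[3L]] - t0
  }

  theta <- if (mode == "ekf") state$x[-1L] else state$x
  par <- phm_split_theta(theta, orders)
  structure(
    list(a = par$a, d = par$d, theta = theta, orders = orders,
         lambda = lambda, mode = mode, state = state,
         u_scale = u_scale, tau_scale = tau_scale,
         y_hat = y_hat * tau_scale, n = N, per_loop_time = times),
    class = "phm_fit"
  )
}

#' @export
print.phm_fit <- function(x, ...) {
  cat(sprintf(
    "<phm_fit> %s, orders l=%d m=%d n=%d, lambda=%.3g, %d loops\n",
    x$mode, x$orders[["l"]], x$orders[["m"]], x$orders[["n"]], x$lambda, x$n
  ))
  cat("  a:", format(x$a, digits = 4), "\n")
  cat("  d:", format(as.vector(t(x$d)), digits = 4), "\n")
  invisible(x)
}

# Core PHM free-run recursion on the normalized scale: y[t] for t in
# from..N, earlier entries of y are seeds; indices < 1 contribute 0.
phm_recurse <- function(un, yn, a, d, from) {
  l <- length(a); m <- nrow(d); n <- ncol(d)
  N <- length(un)
  for (t in from:N) {
    acc <- 0
    for (i in seq_len(l)) {
      if (t - i >= 1L) acc <- acc + a[i] * yn[t - i]
    }
    for (i in seq_len(m)) {
      ui <- if (t - i >= 1L) un[t - i] else 0
      if (ui != 0) acc <- acc + sum(d[i, ] * poly_basis(ui, n))
    }
    if (!is.finite(acc)) stopf("free-run diverged at loop %d", t)
    yn[t] <- acc
  }
  yn
}

#' Frozen-parameter free-run torque prediction with the PHM
#'
#' Iterates the identified Hammerstein recursion feeding predicted outputs
#' back in place of measurements; parameters stay frozen. Measured torque is
#' never read beyond the seed values.
#'
#' @param u MAV series over the prediction span (mV, absolute scale).
#' @param fit a `phm_fit` from [kf_identify()].
#' @param y_init seed torques (Nm): the last `l` measured values before the
#'   prediction span, oldest first. Shorter seeds are zero-padded on the left.
#' @param u_hist the last `m` MAV values before the prediction span, oldest
#'   first (zero-padded when omitted).
#' @return predicted torque series (Nm), same length as `u`.
#' @export
kf_free_run_predict <- function(u, fit, y_init = numeric(0),
                                u_hist = numeric(0)) {
  stopifnot(inherits(fit, "phm_fit"))
  l <- fit$orders[["l"]]; m <- fit$orders[["m"]]
  pad <- max(l, m)
  take_last <- function(v, n) {
    v <- c(numeric(max(0L, n - length(v))), v)
    v[seq.int(length(v) - n + 1L, length(v))]
  }
  y_init <- take_last(y_init, l)
  u_hist <- take_last(u_hist, m)

  un <- c(numeric(pad - m), u_hist, u) / fit$u_scale
  yn <- c(numeric(pad - l), y_init / fit$tau_scale, numeric(length(u)))
  yn <- phm_recurse(un, yn, fit$a, fit$d, from = pad + 1L)
  yn[pad + seq_along(u)] * fit$tau_scale
}
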