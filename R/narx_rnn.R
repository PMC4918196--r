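# NARX torque model with bilinear input-output cross terms:
#
#   tau(t) = sum_{r=1..l} v_r tau(t-r)
#          + sum_{i=1..m} sum_{j=1..n} w_ij u^j(t-i)
#          + a u(t-m) tau(t-1) + b u(t-1) tau(t-l)
#
# identified once, at the end of the identification phase, as the
# minimum-norm least-squares solution D^+ tau of the stacked regression
# (pseudoinverse of the design matrix D), then run free (feeding its own
# predictions back) with frozen parameters. Indices before the series start
# contribute zero.

#' NARX parameter set
#'
#' @param v output-lag coefficients `v_r`, length `l`.
#' @param w input-power coefficient matrix (`m x n`), `w[i, j]` multiplying
#'   `u^j(t-i)`.
#' @param a,b bilinear cross-term coefficients multiplying
#'   `u(t-m) tau(t-1)` and `u(t-1) tau(t-l)`.
#' @param k_id identification horizon (number of loops used), `NA` for
#'   hand-built parameter sets.
#' @return an object of class `narx_fit`.
#' @export
narx_parameters <- function(v, w, a, b, k_id = NA_integer_) {
  w <- as.matrix(w)
  if (any(!is.finite(c(v, w, a, b)))) stopf("coefficients must be finite")
  structure(
    list(v = as.numeric(v), w = w, a = as.numeric(a), b = as.numeric(b),
         orders = c(l = length(v), m = nrow(w), n = ncol(w)),
         k_id = k_id),
    class = "narx_fit"
  )
}

#' @export
print.narx_fit <- function(x, ...) {
  cat(sprintf(
    "<narx_fit> orders l=%d m=%d n=%d, k_id=%s\n",
    x$orders[["l"]], x$orders[["m"]], x$orders[["n"]],
    ifelse(is.na(x$k_id), "-", x$k_id)
  ))
  cat("  v:", format(x$v, digits = 4), " a:", format(x$a, digits = 4),
      " b:", format(x$b, digits = 4), "\n")
  cat("  w:", format(as.vector(t(x$w)), digits = 4), "\n")
  invisible(x)
}

#' Build the NARX identification design matrix
#'
#' Row `t` (0-based time, `t = 1 .. N-1` for an `N`-sample series) stacks the
#' regressor blocks `[Y, X_1 .. X_m, C_1, C_2]`:
#' `[tau(t-1) .. tau(t-l); u^j(t-i) for i = 1..m, j = 1..n;`
#' `u(t-m) tau(t-1); u(t-1) tau(t-l)]`, with indices before the series start
#' contributing zero; the target is `tau(t)`.
#'
#' @param u MAV series (times `0 .. N-1`).
#' @param tau torque series, same length.
#' @param orders `c(l, m, n)` (default `c(2, 2, 2)`).
#' @return an object of class `narx_design`: list with `D`
#'   (`(N-1) x (l + m n + 2)` matrix), `target` (`tau(1) .. tau(N-1)`), and
#'   `orders`.
#' @export
build_design_matrix <- function(u, tau, orders = c(2, 2, 2)) {
  orders <- phm_orders(orders)
  u <- as.numeric(u); tau <- as.numeric(tau)
  if (length(u) != length(tau)) stopf("alignment error")
  N <- length(u)
  if (N < 1L) stopf("alignment error")
  l <- orders[["l"]]; m <- orders[["m"]]; n <- orders[["n"]]
  p <- l + m * n + 2L
  nr <- N - 1L
  D <- matrix(0, nrow = nr, ncol = p)
  lagv <- function(x, i) {
    # x(t - i) for targets t = 1 .. N-1, zero before the series start
    idx <- seq_len(nr) - i + 1L   # R positions of time t - i
    out <- numeric(nr)
    ok <- idx >= 1L
    out[ok] <- x[idx[ok]]
    out
  }
  col <- 0L
  for (r in seq_len(l)) {
    D[, col + r] <- lagv(tau, r)
  }
  col <- l
  for (i in seq_len(m)) {
    ui <- lagv(u, i)
    for (j in seq_len(n)) {
      D[, col + j] <- ui^j
    }
    col <- col + n
  }
  D[, col + 1L] <- lagv(u, m) * lagv(tau, 1L)
  D[, col + 2L] <- lagv(u, 1L) * lagv(tau, l)
  structure(
    list(D = D, target = if (nr > 0L) tau[2:N] else numeric(0),
         orders = orders),
    class = "narx_design"
  )
}

#' One-shot NARX identification by pseudoinverse
#'
#' Minimum-norm least-squares solution `D^+ target`, with the pseudoinverse
#' computed by SVD and singular values below `max(dim) * eps * sigma_max`
#' treated as zero (robust to the collinearity of polynomial regressors).
#'
#' @param design a `narx_design` from [build_design_matrix()].
#' @return an object of class `narx_fit` (see [narx_parameters()]), with
#'   `k_id` set to the number of loops spanned by the design.
#' @export
identify_narx <- function(design) {
  stopifnot(inherits(design, "narx_design"))
  if (nrow(design$D) == 0L) stopf("no identification data")
  theta <- as.numeric(pinv(design$D) %*% design$target)
  l <- design$orders[["l"]]; m <- design$orders[["m"]]
  n <- design$orders[["n"]]
  narx_parameters(
    v = theta[seq_len(l)],
    w = matrix(theta[l + seq_len(m * n)], nrow = m, ncol = n, byrow = TRUE),
    a = theta[l + m * n + 1L],
    b = theta[l + m * n + 2L],
    k_id = nrow(design$D) + 1L
  )
}

# Core recursion: fill tau[from..N] (R positions; position p = time p-1)
# from the NARX equation, reading earlier tau entries (seeds or previous
# predictions) and u; indices < 1 contribute 0.
narx_recurse <- function(u, tau, par, from) {
  l <- par$orders[["l"]]; m <- par$orders[["m"]]; n <- par$orders[["n"]]
  N <- length(u)
  at <- function(x, idx) if (idx >= 1L) x[idx] else 0
  for (t in from:N) {
    acc <- 0
    for (r in seq_len(l)) acc <- acc + par$v[r] * at(tau, t - r)
    for (i in seq_len(m)) {
      ui <- at(u, t - i)
      if (ui != 0) acc <- acc + sum(par$w[i, ] * ui^seq_len(n))
    }
    acc <- acc + par$a * at(u, t - m) * at(tau, t - 1L)
    acc <- acc + par$b * at(u, t - 1L) * at(tau, t - l)
    if (!is.finite(acc)) stopf("free-run diverged at loop %d", t - 1L)
    tau[t] <- acc
  }
  tau
}

#' Frozen-parameter free-run NARX prediction
#'
#' Iterates the NARX recursion with predicted torque substituted for measured
#' torque in all lagged and cross terms; parameters stay frozen. The same
#' routine replays a known parameter set exactly when seeded with the true
#' initial history (used as the simulation oracle).
#'
#' @param u MAV series covering the prediction span (absolute scale).
#' @param params a `narx_fit` (identified or hand-built).
#' @param tau_init seed torques: measured values immediately before the
#'   prediction span, oldest first (typically the last `l` identified loops);
#'   zero-padded on the left when shorter than `l`.
#' @param u_hist MAV values immediately before the prediction span, oldest
#'   first (zero-padded when omitted).
#' @return predicted torque series, same length as `u`.
#' @export
narx_free_run_predict <- function(u, params, tau_init = numeric(0),
                                  u_hist = numeric(0)) {
  stopifnot(inherits(params, "narx_fit"))
  l <- params$orders[["l"]]; m <- params$orders[["m"]]
  pad <- max(l, m)
  take_last <- function(v, n) {
    v <- c(numeric(max(0L, n - length(v))), v)
    v[seq.int(length(v) - n + 1L, length(v))]
  }
  uu <- c(numeric(pad - m), take_last(u_hist, m), u)
  tt <- c(numeric(pad - l), take_last(tau_init, l), numeric(length(u)))
  tt <- narx_recurse(uu, tt, params, from = pad + 1L)
  tt[pad + seq_along(u)]
}

#' Replay a NARX system from time zero
#'
#' Generates `tau(0) = tau0` and then the NARX recursion for `t >= 1` with
#' zero pre-history — exactly the convention of [build_design_matrix()], so
#' data generated this way from a known parameter set is exactly
#' identifiable (a generate-and-recover oracle).
#'
#' @param u input series (times `0 .. N-1`).
#' @param params a `narx_fit`.
#' @param tau0 initial torque at time 0.
#' @return torque series of the same length as `u`.
#' @export
narx_replay <- function(u, params, tau0 = 0) {
  N <- length(u)
  tau <- c(tau0, numeric(N - 1L))
  if (N >= 2L) tau <- narx_recurse(u, tau, params, from = 2L)
  tau
}
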