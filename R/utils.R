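# Internal numerical helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds halves to even; sample-count conversions in this
#' package use the conventional round-half-up so that loop lengths and window
#' sizes are reproducible integers.
#'
#' @param x numeric vector.
#' @return integer vector, `floor(x + 0.5)`.
#' @keywords internal
#' @noRd
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Moore-Penrose pseudoinverse via SVD
#'
#' Singular values below `max(dim(A)) * eps * sigma_max` are treated as zero,
#' giving the minimum-norm least-squares solution on rank-deficient systems.
#'
#' @param A numeric matrix.
#' @param tol singular-value cutoff; default as above.
#' @return the pseudoinverse of `A` (ncol x nrow).
#' @keywords internal
#' @noRd
pinv <- function(A, tol = NULL) {
  A <- as.matrix(A)
  if (length(A) == 0L) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s <- svd(A)
  if (is.null(tol)) {
    tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  }
  keep <- s$d > tol
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Matrix exponential by scaling and squaring
#'
#' Small dense matrices only (used for exact zero-order-hold discretization of
#' the 2x2 torque dynamics); Taylor series after power-of-two scaling.
#'
#' @keywords internal
#' @noRd
expm_small <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  nrmA <- max(abs(A))
  j <- max(0L, ceiling(log2(max(nrmA, .Machine$double.eps))) + 1L)
  As <- A / 2^j
  E <- diag(n)
  term <- diag(n)
  for (k in 1:16) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(j)) E <- E %*% E
  E
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded sub-draws do not
#' disturb the global stream. A `NULL` seed evaluates the code as-is.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# population variance (1/N); both VAF terms use it so the convention cancels
var_pop <- function(x) {
  mean((x - mean(x))^2)
}

stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
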