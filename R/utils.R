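## Internal numerical helpers shared across modules.

#' Solve a symmetric positive-definite system with a one-shot jitter fallback
#'
#' Cholesky solve of `K x = b`. If the factorization fails, 1e-8 is added to
#' the diagonal once; a second failure is an error. This is the package-wide
#' policy for nearly singular relationship matrices.
#'
#' @param K symmetric matrix.
#' @param b right-hand side vector or matrix.
#' @param label name used in error messages.
#' @return the solution, with the same shape as `b`.
#' @keywords internal
#' @noRd
chol_solve <- function(K, b, label = "K") {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(K + diag(1e-8, nrow(K))), error = function(e) NULL)
    if (is.null(ch)) {
      stop(sprintf("matrix '%s' is singular even after 1e-8 diagonal jitter", label))
    }
  }
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}

#' @noRd
stopifnot_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  ok <- length(x) == 1L && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) {
    stop(sprintf(
      "'%s' must be a single value in %s0, 1%s", name,
      if (open_left) "(" else "[", if (open_right) ")" else "]"
    ))
  }
  invisible(x)
}

#' Mean of off-diagonal elements
#' @noRd
offdiag_mean <- function(M) {
  n <- nrow(M)
  if (n < 2L) return(NA_real_)
  (sum(M) - sum(diag(M))) / (n * (n - 1L))
}

#' Upper-triangle (i < j) pairs of a symmetric matrix as a vector
#' @noRd
upper_vec <- function(M) M[upper.tri(M)]
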