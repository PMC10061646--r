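#' Minimum-norm least-squares solve via the Moore-Penrose pseudoinverse
#'
#' Solves `A X ~ B` for `X`. With `ridge = 0` this is the SVD-based
#' minimum-norm least-squares solution `A^+ B`, the closed-form training
#' step shared by all three randomized network members: singular values
#' below `rtol * max(singular value)` are treated as zero. With `ridge > 0`
#' the Tikhonov-regularized solution `(A'A + ridge I)^{-1} A'B` is returned
#' instead.
#'
#' @param A numeric matrix, N x k (design / hidden activations).
#' @param B numeric matrix or vector, N rows (targets).
#' @param ridge nonnegative ridge penalty; 0 (default) uses the plain
#'   pseudoinverse.
#' @param rtol relative singular-value cutoff.
#' @return k x m numeric matrix of coefficients.
#' @examples
#' A <- matrix(c(1, 0, 0, 2), 2, 2)
#' pinv_solve(A, matrix(c(1, 2), 2, 1))  # exact diagonal solve: c(1, 1)
#' @export
pinv_solve <- function(A, B, ridge = 0, rtol = 1e-10) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (nrow(A) != nrow(B)) {
    stop("pinv_solve: row-count mismatch (A has ", nrow(A),
         " rows, B has ", nrow(B), ")")
  }
  if (!all(is.finite(A)) || !all(is.finite(B))) {
    stop("pinv_solve: non-finite entries in input")
  }
  if (length(ridge) != 1 || !is.finite(ridge) || ridge < 0) {
    stop("pinv_solve: ridge must be a single nonnegative number")
  }
  if (ridge > 0) {
    k <- ncol(A)
    return(solve(crossprod(A) + diag(ridge, k), crossprod(A, B)))
  }
  sv <- svd(A)
  dmax <- if (length(sv$d)) max(sv$d) else 0
  keep <- sv$d > rtol * dmax
  if (!any(keep)) {
    return(matrix(0, ncol(A), ncol(B)))
  }
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  V %*% (crossprod(U, B) / sv$d[keep])
}
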