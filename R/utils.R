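## Small linear-algebra helpers shared across the package.  All routines work
## transparently for real and complex (Hermitian) matrices.

#' Conjugate transpose
#' @param M matrix
#' @return the conjugate transpose of `M`
#' @keywords internal
ct <- function(M) Conj(t(M))

#' Matrix trace of a product, Tr(AB)
#'
#' Equals `sum(A * t(B))`; avoids forming the product.
#' @param A,B conformable matrices
#' @return scalar (complex if inputs are complex)
#' @keywords internal
tr_prod <- function(A, B) sum(A * t(B))

#' Frobenius inner product Re Tr(A^H B)
#' @param A,B conformable matrices
#' @return real scalar
#' @keywords internal
frob_inner <- function(A, B) Re(sum(Conj(A) * B))

#' Frobenius norm
#' @param A matrix
#' @return nonnegative real
#' @keywords internal
frob_norm <- function(A) sqrt(sum(abs(A)^2))

#' Blockwise Frobenius inner product
#'
#' Accumulated over all blocks as if the blocks were one big block-diagonal
#' matrix: Re sum_b Tr(A_b^H B_b).
#' @param A,B lists of conformable matrices
#' @return real scalar
#' @keywords internal
block_inner <- function(A, B) {
  stopifnot(length(A) == length(B))
  s <- 0
  for (b in seq_along(A)) s <- s + frob_inner(A[[b]], B[[b]])
  s
}

#' Blockwise Frobenius norm
#' @param A list of matrices
#' @return nonnegative real
#' @keywords internal
block_fnorm <- function(A) {
  sqrt(sum(vapply(A, function(M) sum(abs(M)^2), numeric(1))))
}

#' Symmetrize (Hermitize) a matrix
#' @param M square matrix
#' @return (M + M^H)/2
#' @keywords internal
hermitize <- function(M) (M + ct(M)) / 2

## Hermiticity check with a warn/error ladder.  Deviations are measured
## relative to the matrix norm; below `warn_tol` the matrix passes silently,
## between `warn_tol` and `err_tol` a warning is issued, above `err_tol`
## an error is raised.
check_hermitian <- function(M, what = "matrix",
                            warn_tol = 1e-10, err_tol = 1e-6) {
  dev <- frob_norm(M - ct(M))
  scale <- max(frob_norm(M), 1)
  rel <- dev / scale
  if (rel > err_tol) {
    stop(sprintf("%s deviates from Hermiticity by %.3e (relative)", what, rel))
  }
  if (rel > warn_tol) {
    warning(sprintf("%s deviates from Hermiticity by %.3e (relative)",
                    what, rel))
  }
  invisible(TRUE)
}

check_unitary <- function(C, what = "orbital coefficients",
                          warn_tol = 1e-10, err_tol = 1e-6) {
  n <- ncol(C)
  dev <- frob_norm(ct(C) %*% C - diag(n)) / max(sqrt(n), 1)
  if (dev > err_tol) {
    stop(sprintf("%s deviate from unitarity by %.3e", what, dev))
  }
  if (dev > warn_tol) {
    warning(sprintf("%s deviate from unitarity by %.3e", what, dev))
  }
  invisible(TRUE)
}

#' Eigendecomposition of a Hermitian matrix with ascending eigenvalues
#'
#' Base `eigen()` returns eigenvalues in decreasing order; Roothaan updates
#' and Aufbau filling want them ascending.
#' @param M Hermitian matrix (real symmetric or complex Hermitian)
#' @return list with `values` (ascending, real) and `vectors`
#' @keywords internal
eigen_ascending <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  idx <- rev(seq_along(e$values))
  list(values = Re(e$values[idx]), vectors = e$vectors[, idx, drop = FALSE])
}
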