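## Orthonormalization helpers.  The optimizer consumes the SCF problem in an
## orthonormal orbital basis; when the caller's basis has an overlap matrix
## S != I, a transformation X with X^H S X = I reduces the generalized
## Roothaan problem F C = S C E to a standard eigenproblem.  Three standard
## constructions are provided: symmetric (Loewdin), canonical (drops
## near-null overlap eigenvectors), and a pivoted-Cholesky pre-selection of
## a well-conditioned basis-function subset.

new_orthogonalizer <- function(X, method, dropped = integer(0)) {
  structure(list(X = X, method = method, dropped = dropped),
            class = "orthogonalizer")
}

#' @export
print.orthogonalizer <- function(x, ...) {
  cat(sprintf("<orthogonalizer> %s: %d x %d%s\n", x$method,
              nrow(x$X), ncol(x$X),
              if (length(x$dropped)) sprintf(" (%d dropped)", length(x$dropped))
              else ""))
  invisible(x)
}

#' Symmetric (Loewdin) orthogonalization
#'
#' `X = S^(-1/2)` via eigendecomposition; square, with `X^H S X = I`.
#' Requires a positive-definite overlap; for (near-)singular `S` use
#' [canonical_x()].
#'
#' @param S Hermitian positive-definite overlap matrix
#' @return an `orthogonalizer`
#' @export
symmetric_x <- function(S) {
  check_hermitian(S, "overlap matrix")
  e <- eigen(hermitize(S), symmetric = TRUE)
  vals <- Re(e$values)
  if (any(vals <= 1e-14 * max(vals))) {
    stop("overlap matrix is numerically singular; use canonical_x()")
  }
  X <- e$vectors %*% ((1 / sqrt(vals)) * ct(e$vectors))
  new_orthogonalizer(X, "symmetric")
}

#' Canonical orthogonalization with linear-dependence removal
#'
#' Keeps overlap eigenpairs with eigenvalue above `drop_threshold` and
#' returns `X` with columns `u_i / sqrt(s_i)`; `X` is `n x k` with
#' `X^H S X = I_k`.
#'
#' @param S Hermitian positive-semidefinite overlap matrix
#' @param drop_threshold eigenvalue cutoff (default `1e-5`)
#' @return an `orthogonalizer`; `dropped` records removed eigenvalues
#' @export
canonical_x <- function(S, drop_threshold = 1e-5) {
  check_hermitian(S, "overlap matrix")
  e <- eigen(hermitize(S), symmetric = TRUE)
  vals <- Re(e$values)
  keep <- vals > drop_threshold
  if (!any(keep)) stop("all overlap eigenvalues below the drop threshold")
  X <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(vals[keep]), sum(keep))
  new_orthogonalizer(X, "canonical", dropped = vals[!keep])
}

#' Pivoted-Cholesky selection of a well-conditioned function subset
#'
#' Greedy pivoted Cholesky decomposition of the overlap matrix, stopping
#' when the largest remaining diagonal residual drops below
#' `pivot_threshold` times the largest initial diagonal (a relative, hence
#' scale-invariant, criterion).  The returned indices define a reduced
#' basis-function subset whose Gram matrix is well conditioned; exact
#' duplicates of already-selected functions have zero residual and are never
#' picked.  Conventional orthonormalization is then applied to the subset.
#'
#' @param S Hermitian positive-semidefinite overlap matrix
#' @param pivot_threshold relative stopping threshold (default `1e-8`)
#' @return integer vector of selected (pivot) indices, in pivot order
#' @export
cholesky_pivot_select <- function(S, pivot_threshold = 1e-8) {
  check_hermitian(S, "overlap matrix")
  n <- nrow(S)
  d <- Re(diag(S))
  scale <- max(d)
  L <- matrix(if (is.complex(S)) 0 + 0i else 0, n, 0)
  sel <- integer(0)
  repeat {
    p <- which.max(d)
    if (d[p] < pivot_threshold * scale || length(sel) == n) break
    col <- S[, p]
    if (ncol(L) > 0) col <- col - L %*% Conj(L[p, ])
    col <- col / sqrt(d[p])
    L <- cbind(L, col)
    d <- d - abs(col)^2
    d[p] <- -Inf                      # never re-pick a pivot
    sel <- c(sel, p)
  }
  sel
}

#' Solve a generalized Roothaan eigenproblem through an orthogonalizer
#'
#' Transforms `F C = S C E` to the standard problem
#' `(X^H F X) C' = C' E` and back-transforms `C = X C'`.  Utility for
#' callers working in a nonorthonormal basis and for validating the
#' orthogonalizers against a direct generalized solver.
#'
#' @param F Hermitian matrix in the caller's basis
#' @param ortho an `orthogonalizer` for the basis overlap
#' @return list with ascending `values` and coefficient matrix `vectors`
#'   satisfying `vectors^H S vectors = I`
#' @export
solve_generalized_roothaan <- function(F, ortho) {
  X <- ortho$X
  Fo <- hermitize(ct(X) %*% F %*% X)
  e <- eigen_ascending(Fo)
  list(values = e$values, vectors = X %*% e$vectors)
}
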