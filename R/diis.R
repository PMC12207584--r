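## Pulay DIIS: the commutator orbital-error metric, error norms, and the
## constrained linear solve for the extrapolation weights, including
## Hamilton-Pulay diagonal damping, normalization by the smallest diagonal,
## and Chupin-style restart screening of stale error vectors.

#' Commutator orbital error e = [F, P]
#'
#' Vanishes exactly at self-consistency; its off-diagonal elements in the
#' orbital basis are orbital rotation gradients.  Both matrices must live in
#' the same orthonormal basis.  The result is anti-Hermitian.
#'
#' @param F,P Hermitian matrices of equal dimension
#' @return the matrix `FP - PF`
#' @export
commutator_error <- function(F, P) {
  if (!all(dim(F) == dim(P))) {
    stop("F and P have mismatched dimensions")
  }
  F %*% P - P %*% F
}

#' Norm of a set of per-block error matrices
#'
#' `"rms"` is the root-mean-square over all matrix elements of all blocks
#' (normalized by the total element count, so duplicating a block leaves the
#' value unchanged); `"max"` is the largest absolute element across blocks.
#' The max norm is intensive in system size, which is why it gates the
#' optimal-damping fallback.
#'
#' @param errors list of per-block error matrices
#' @param kind `"rms"` (default) or `"max"`
#' @return nonnegative real; zero iff every element is zero
#' @export
error_norm <- function(errors, kind = c("rms", "max")) {
  kind <- match.arg(kind)
  stopifnot(length(errors) >= 1)
  if (kind == "rms") {
    ss <- sum(vapply(errors, function(e) sum(abs(e)^2), numeric(1)))
    ne <- sum(vapply(errors, length, integer(1)))
    sqrt(ss / ne)
  } else {
    max(vapply(errors, function(e) max(abs(e)), numeric(1)))
  }
}

#' DIIS error-overlap (Gram) matrix
#'
#' `B_ij = Re sum_blocks Tr(e_i^H e_j)`.  The real part is taken so that B
#' is real symmetric also for complex orbitals (the imaginary part of the
#' trace inner product is antisymmetric and carries no information for the
#' symmetric weight solve).  B is positive semidefinite by construction.
#'
#' @param errors list (length m) of per-block error-matrix lists
#' @return m x m real symmetric matrix
#' @export
diis_b_matrix <- function(errors) {
  m <- length(errors)
  B <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      B[i, j] <- B[j, i] <- block_inner(errors[[i]], errors[[j]])
    }
  }
  B
}

#' DIIS extrapolation weights from an error-overlap matrix
#'
#' Minimizes `c^T B c` subject to `sum(c) = 1` via the bordered linear
#' system; before solving, the error vectors are screened (entry `i` is kept
#' only if `delta_diis * B_ii <= min_j B_jj`; the most recent entry is always
#' kept so the extrapolation contains the newest Fock matrix), B is
#' normalized by its smallest kept diagonal element (or by the newest one,
#' see `normalize`), and the diagonal is damped by the factor `1 + d`.
#' Screened-out entries receive weight zero; weights may be negative but
#' always sum to one.  A singular system falls back to weight one on the
#' most recent entry with a warning.
#'
#' @param B m x m real symmetric error-overlap matrix
#' @param d Hamilton-Pulay damping factor (default 0.02)
#' @param delta_diis screening parameter (default `1e-4`; 0 disables
#'   screening)
#' @param newest index of the most recent entry (default `m`... callers with
#'   lowest-energy-first history ordering must pass it explicitly)
#' @param normalize `"smallest"` (default) or `"newest"` diagonal element
#' @return numeric weight vector of length m
#' @export
diis_weights_from_b <- function(B, d = 0.02, delta_diis = 1e-4,
                                newest = nrow(B),
                                normalize = c("smallest", "newest")) {
  normalize <- match.arg(normalize)
  m <- nrow(B)
  stopifnot(ncol(B) == m, newest >= 1, newest <= m)
  if (m == 1L) return(1)
  dg <- diag(B)
  keep <- delta_diis * dg <= min(dg)
  keep[newest] <- TRUE
  kept <- which(keep)
  Bk <- B[kept, kept, drop = FALSE]
  scale <- if (normalize == "smallest") min(diag(Bk)) else B[newest, newest]
  if (scale > 0) Bk <- Bk / scale
  diag(Bk) <- diag(Bk) * (1 + d)
  k <- length(kept)
  A <- rbind(cbind(Bk, rep(-1, k)), c(rep(-1, k), 0))
  rhs <- c(rep(0, k), -1)
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  w <- numeric(m)
  if (is.null(sol) || any(!is.finite(sol))) {
    warning("singular DIIS system; falling back to the most recent entry")
    w[newest] <- 1
    return(w)
  }
  w[kept] <- sol[seq_len(k)]
  w
}

#' DIIS weights from error matrices
#'
#' Convenience wrapper building the overlap matrix with [diis_b_matrix()]
#' and solving with [diis_weights_from_b()].
#'
#' @inheritParams diis_b_matrix
#' @inheritParams diis_weights_from_b
#' @return numeric weight vector, one per error set, summing to one
#' @export
diis_weights <- function(errors, d = 0.02, delta_diis = 1e-4,
                         newest = length(errors),
                         normalize = c("smallest", "newest")) {
  diis_weights_from_b(diis_b_matrix(errors), d = d, delta_diis = delta_diis,
                      newest = newest, normalize = match.arg(normalize))
}
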