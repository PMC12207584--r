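## EDIIS and ADIIS.  Far from convergence DIIS is unreliable; EDIIS and
## ADIIS instead minimize proxy energy models over *interpolation* weights
## (nonnegative, summing to one, i.e. the unit simplex).  Both models are
## quadratic forms f(x) = 1/2 x^T A x + b.x + const; they are minimized with
## a robust Powell-style sequence of exact pairwise line searches toward the
## simplex vertices.  The unconstrained square-ratio parametrization is
## deliberately not used: it destroys convexity and stalls line searches.

#' Quadratic form on the unit simplex
#'
#' Represents `f(x) = 1/2 x^T A x + b . x + const`; `A` is symmetrized on
#' construction.
#'
#' @param A m x m real matrix (symmetrized)
#' @param b length-m real vector
#' @param const real offset (default 0)
#' @return an object of class `simplex_quadratic`
#' @export
simplex_quadratic <- function(A, b, const = 0) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), length(b) == nrow(A))
  structure(list(A = (A + t(A)) / 2, b = as.numeric(b),
                 const = as.numeric(const)),
            class = "simplex_quadratic")
}

#' Evaluate a simplex quadratic
#' @param q a [simplex_quadratic()]
#' @param x weight vector
#' @return the value of the quadratic form at `x`
#' @export
eval_simplex_quadratic <- function(q, x) {
  0.5 * sum(x * (q$A %*% x)) + sum(q$b * x) + q$const
}

## Inner product accumulated over all blocks of a history entry pair.
history_inner <- function(Alist, Blist) block_inner(Alist, Blist)

#' EDIIS proxy-energy objective
#'
#' For history entries with energies `E_i`, Fock matrices `F_i` and density
#' matrices `P_i` (per block, accumulated over all particle types), the
#' EDIIS model of the energy of the mixed density `sum_i c_i P_i` is
#' `f(c) = sum_i c_i E_i - 1/2 sum_{i<j} c_i c_j X_ij` with
#' `X_ij = <F_i - F_j | P_i - P_j>`.  For energies that are exactly
#' quadratic in the density (Hartree-Fock form) this model is *exact*:
#' it reproduces `E(sum c_i P_i)` for every simplex point `c`.
#'
#' @param energies numeric vector of total energies `E_i`
#' @param F_list list (length m) of per-block Fock-matrix lists
#' @param P_list list (length m) of per-block density-matrix lists
#' @return a [simplex_quadratic()] with `A = -X/2` and `b = E`
#' @export
ediis_objective <- function(energies, F_list, P_list) {
  m <- length(energies)
  stopifnot(length(F_list) == m, length(P_list) == m)
  X <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      dF <- mapply(function(a, b) a - b, F_list[[i]], F_list[[j]],
                   SIMPLIFY = FALSE)
      dP <- mapply(function(a, b) a - b, P_list[[i]], P_list[[j]],
                   SIMPLIFY = FALSE)
      X[i, j] <- X[j, i] <- history_inner(dF, dP)
    }
  }
  ## f(c) = c.E - 1/2 sum_{i<j} c_i c_j X_ij = c.E - 1/4 c^T X c,
  ## so in the 1/2 x^T A x normal form A = -X/2.
  simplex_quadratic(-X / 2, energies, 0)
}

#' ADIIS proxy-energy objective
#'
#' The augmented-DIIS model around reference entry `n`:
#' `f(c) = E_n + 2 sum_i c_i <P_i - P_n | F_n>
#'       + sum_ij c_i c_j <P_i - P_n | F_j - F_n>`,
#' inner products accumulated over particle types.  For quadratic (HF-form)
#' energies this equals `E_n + 2 [E(sum c_i P_i) - E_n]`, so its simplex
#' minimizer coincides with the EDIIS one.
#'
#' @inheritParams ediis_objective
#' @param ref_index index `n` of the reference entry (the most recent Fock
#'   evaluation in the driver)
#' @return a [simplex_quadratic()]
#' @export
adiis_objective <- function(energies, F_list, P_list, ref_index) {
  m <- length(energies)
  stopifnot(ref_index >= 1, ref_index <= m)
  Fn <- F_list[[ref_index]]
  Pn <- P_list[[ref_index]]
  D <- lapply(P_list, function(P) {
    mapply(function(a, b) a - b, P, Pn, SIMPLIFY = FALSE)
  })
  dF <- lapply(F_list, function(F) {
    mapply(function(a, b) a - b, F, Fn, SIMPLIFY = FALSE)
  })
  b <- vapply(D, function(Di) 2 * history_inner(Di, Fn), numeric(1))
  M <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      M[i, j] <- history_inner(D[[i]], dF[[j]])
    }
  }
  simplex_quadratic(M + t(M), b, energies[ref_index])
}

#' Minimize a quadratic form on the unit simplex
#'
#' Powell-style coordinate scheme: starting from the best of the vertices,
#' the centroid and slightly offset points, repeatedly performs exact
#' pairwise line searches `x <- (1 - lambda) x + lambda e_i` toward each
#' vertex, with `lambda` from the closed-form one-dimensional quadratic
#' restriction clamped to `(0, 1]` (a full step is taken when the
#' restriction has nonpositive curvature but negative slope).  Sweeps stop
#' when the objective changes by less than `tol` (relative) or after
#' `max_sweeps` sweeps.  The iterate never leaves the simplex and the
#' objective never increases.
#'
#' @param q a [simplex_quadratic()]
#' @param tol relative objective-change tolerance (default `1e-12`)
#' @param max_sweeps maximal number of sweeps (default `10 * m`)
#' @return weight vector on the unit simplex
#' @export
minimize_on_simplex <- function(q, tol = 1e-12, max_sweeps = NULL) {
  m <- length(q$b)
  if (!all(is.finite(q$A)) || !all(is.finite(q$b)) || !is.finite(q$const)) {
    stop("non-finite entries in simplex quadratic")
  }
  if (m == 1L) return(1)
  if (is.null(max_sweeps)) max_sweeps <- 10L * m
  ## candidate start points: vertices, centroid, offset points, and edge
  ## midpoints (the latter catch basins living on the simplex edges)
  starts <- c(lapply(seq_len(m), function(i) { x <- numeric(m); x[i] <- 1; x }),
              list(rep(1 / m, m)),
              lapply(seq_len(m), function(i) {
                x <- rep(1 / (m + 2), m); x[i] <- 3 / (m + 2); x
              }))
  if (m >= 3) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        x <- numeric(m); x[i] <- 0.5; x[j] <- 0.5
        starts <- c(starts, list(x))
      }
    }
  }
  ## a coarse deterministic simplex grid bounds the basin radius for badly
  ## indefinite objectives; negligible cost at history-length dimensions
  if (m <= 6) {
    G <- simplex_grid_points(m, 6L)
    starts <- c(starts, lapply(seq_len(ncol(G)), function(k) G[, k]))
  }
  A <- q$A
  b <- q$b
  descend <- function(x) {
    f <- eval_simplex_quadratic(q, x)
    for (sweep in seq_len(max_sweeps)) {
      f_before <- f
      for (i in seq_len(m)) {
        d <- -x
        d[i] <- d[i] + 1                   # direction e_i - x
        g <- sum(d * (A %*% x + b))        # directional derivative
        h <- sum(d * (A %*% d))            # curvature along d
        ## exact 1-D restriction f(lam) = f + g lam + h lam^2 / 2 on (0, 1]:
        ## interior stationary point for h > 0, else the full step whenever
        ## it descends (g + h/2 < 0 escapes interior saddles of indefinite
        ## objectives, where g = 0 but the curvature toward a vertex is < 0)
        lam <- if (h > 0) {
          min(max(-g / h, 0), 1)
        } else if (g + h / 2 < 0) 1 else 0
        if (lam > 0) {
          x <- (1 - lam) * x + lam * (seq_len(m) == i)
          x[x < 0] <- 0
          x <- x / sum(x)
        }
      }
      ## weight-transfer searches along the edge directions e_i - e_j
      ## (feasible for lam in (0, x_j]); these span the tangent directions
      ## the vertex moves miss, e.g. negative-curvature escapes at interior
      ## saddle points of indefinite objectives
      for (j in seq_len(m)) {
        if (x[j] <= 0) next
        for (i in seq_len(m)) {
          if (i == j) next
          d <- numeric(m); d[i] <- 1; d[j] <- -1
          g <- sum(d * (A %*% x + b))
          h <- sum(d * (A %*% d))
          lam <- if (h > 0) min(max(-g / h, 0), x[j])
                 else if (g + h * x[j] / 2 < 0) x[j] else 0
          if (lam > 0) {
            x[i] <- x[i] + lam
            x[j] <- x[j] - lam
            if (x[j] <= 0) break
          }
        }
      }
      x[x < 0] <- 0
      x <- x / sum(x)
      f <- eval_simplex_quadratic(q, x)
      if (abs(f_before - f) <= tol * (abs(f_before) + 1)) break
    }
    list(x = x, f = f)
  }
  ## indefinite objectives have several basins: descend from every start
  ## point and keep the best (the convex case converges from any of them)
  best <- NULL
  for (x0 in starts) {
    res <- descend(x0)
    if (is.null(best) || res$f < best$f) best <- res
  }
  best$x
}

#' Dense simplex-grid reference minimizer
#'
#' Brute-force oracle: evaluates the quadratic on every rational grid point
#' `k / steps` (k integer compositions) of the unit simplex and returns the
#' best.  Exponential in `m`; intended for m <= 4 validation only.
#'
#' @param q a [simplex_quadratic()]
#' @param steps grid resolution (default 200, i.e. step 1/200)
#' @return list with elements `x` (grid minimizer) and `value`
#' @export
simplex_grid_minimum <- function(q, steps = 200L) {
  m <- length(q$b)
  X <- simplex_grid_points(m, steps)
  v <- 0.5 * colSums(X * (q$A %*% X)) + colSums(q$b * X) + q$const
  k <- which.min(v)
  list(x = X[, k], value = v[k])
}

## Cache of integer composition grids (columns sum to 1 after scaling).
.simplex_grid_cache <- new.env(parent = emptyenv())

simplex_grid_points <- function(m, steps) {
  key <- paste0(m, "_", steps)
  if (!is.null(.simplex_grid_cache[[key]])) return(.simplex_grid_cache[[key]])
  S <- as.integer(steps)
  if (m == 1L) {
    X <- matrix(1, 1, 1)
  } else if (m == 2L) {
    a <- 0:S
    X <- rbind(a, S - a) / S
  } else {
    ## enumerate the first m-2 coordinates, filter, last two from remainder
    grids <- rep(list(0:S), m - 1L)
    G <- as.matrix(do.call(expand.grid, grids))
    G <- G[rowSums(G) <= S, , drop = FALSE]
    X <- t(cbind(G, S - rowSums(G))) / S
  }
  dimnames(X) <- NULL
  .simplex_grid_cache[[key]] <- X
  X
}

#' Minimal-error-sampling choice between EDIIS and ADIIS candidates
#'
#' Given the two interpolation weight vectors, picks the one whose mixed
#' density `sum_i c_i P_i` changes the current density least in Frobenius
#' norm (accumulated over blocks and particle types).  Ties go to ADIIS.
#'
#' @param c_ediis,c_adiis candidate weight vectors on the simplex
#' @param P_list list (length m) of per-block density-matrix lists
#' @param P_current per-block density-matrix list of the current iterate
#' @return list with `label` (`"ediis"` or `"adiis"`) and `weights`
#' @export
mesa_select <- function(c_ediis, c_adiis, P_list, P_current) {
  mix <- function(w) {
    lapply(seq_along(P_current), function(b) {
      Reduce(`+`, mapply(function(wi, P) wi * P[[b]], w, P_list,
                         SIMPLIFY = FALSE))
    })
  }
  dist <- function(w) {
    Pm <- mix(w)
    sqrt(sum(vapply(seq_along(Pm), function(b) {
      sum(abs(P_current[[b]] - Pm[[b]])^2)
    }, numeric(1))))
  }
  de <- dist(c_ediis)
  da <- dist(c_adiis)
  if (da <= de) list(label = "adiis", weights = c_adiis)
  else list(label = "ediis", weights = c_ediis)
}
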