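## Synthetic SCF test problems.  Real molecular Fock builds are out of scope;
## what the optimizer actually assumes is only that the energy is a smooth
## functional of the densities whose derivative is the Fock matrix.  The
## generators below produce bounded-below *quadratic* (Hartree-Fock-form)
## energy functionals
##
##   E(P) = sum_b Tr(H_b P_b) + 1/2 sum_terms v_k t_i t_j,  t = Tr(A P),
##
## over one or more particle types and symmetry blocks, in real or complex
## arithmetic.  The separable two-body form G[P] = sum_k v_k A_k Tr(A_k P)
## with Hermitian A_k guarantees the adjoint symmetry <A, G_tu[B]> =
## <G_ut[A], B> and (for v_k > 0 within a type) positive semidefiniteness by
## construction, so same-type interactions are repulsive-like and the energy
## is convex in each type's density.  The feasible set (Hermitian densities
## with eigenvalues in [0, f_max] and fixed per-type traces) is compact, so
## every instance is bounded below; this is still verified by sampling at
## construction time.

random_hermitian <- function(n, field = c("real", "complex"), seed = NULL) {
  field <- match.arg(field)
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::rnorm(n * n), n, n)
  if (field == "complex") {
    M <- M + 1i * matrix(stats::rnorm(n * n), n, n)
  }
  hermitize(M)
}

random_unitary <- function(n, field = c("real", "complex"), seed = NULL) {
  ## eigenvectors of a random Hermitian matrix form a Haar-like unitary
  eigen(random_hermitian(n, field, seed), symmetric = TRUE)$vectors
}

new_model_problem <- function(specs, n_particles, H, terms, field, seed) {
  structure(list(specs = specs, n_particles = as.numeric(n_particles),
                 H = H, terms = terms, field = field, seed = seed),
            class = "model_problem")
}

#' @export
print.model_problem <- function(x, ...) {
  cat(sprintf(
    "<model_problem> %s, %d block(s), %d type(s), dims [%s], %d coupling term(s)\n",
    x$field, length(x$specs), length(x$n_particles),
    paste(vapply(x$specs, function(s) s$dim, integer(1)), collapse = ", "),
    length(x$terms)))
  invisible(x)
}

#' Total energy of a model problem at given densities
#'
#' Returned as a complex scalar so callers can verify that the imaginary
#' part vanishes for Hermitian inputs; use `Re()` for the physical value.
#'
#' @param problem a `model_problem`
#' @param P_list per-block density matrices
#' @return complex scalar energy
#' @export
model_energy <- function(problem, P_list) {
  E <- 0 + 0i
  for (b in seq_along(problem$H)) {
    E <- E + tr_prod(problem$H[[b]], P_list[[b]])
  }
  for (tm in problem$terms) {
    ti <- tr_prod(tm$Ai, P_list[[tm$bi]])
    tj <- tr_prod(tm$Aj, P_list[[tm$bj]])
    E <- E + 0.5 * tm$v * ti * tj
  }
  E
}

#' Fock matrices of a model problem at given densities
#'
#' The exact derivative of [model_energy()] with respect to each block's
#' density (verified by finite differences in the test suite).
#'
#' @inheritParams model_energy
#' @return list of per-block Hermitian Fock matrices
#' @export
model_fock <- function(problem, P_list) {
  F <- lapply(problem$H, identity)
  for (tm in problem$terms) {
    ti <- Re(tr_prod(tm$Ai, P_list[[tm$bi]]))
    tj <- Re(tr_prod(tm$Aj, P_list[[tm$bj]]))
    if (tm$bi == tm$bj) {
      ## 1/2 v t^2 with Ai == Aj: dE/dP = v t A
      F[[tm$bi]] <- F[[tm$bi]] + tm$v * ti * tm$Ai
    } else {
      F[[tm$bi]] <- F[[tm$bi]] + 0.5 * tm$v * tj * tm$Ai
      F[[tm$bj]] <- F[[tm$bj]] + 0.5 * tm$v * ti * tm$Aj
    }
  }
  F
}

#' Fock-evaluator closure for a model problem
#'
#' Adapts a `model_problem` to the evaluator contract consumed by
#' [solve_scf()]: a function `(C_list, f_list) -> list(E_total, F, E_imag)`
#' with all matrices in the orthonormal basis.
#'
#' @param problem a `model_problem`
#' @return evaluator function
#' @export
model_evaluator <- function(problem) {
  force(problem)
  function(C_list, f_list) {
    P <- lapply(seq_along(C_list), function(b) {
      build_density(list(C = C_list[[b]], f = f_list[[b]]))
    })
    E <- model_energy(problem, P)
    list(E_total = Re(E), F = model_fock(problem, P), E_imag = Im(E))
  }
}

## Random PSD interaction terms within one block.
intra_terms <- function(block, dim, field, strength, k = dim) {
  lapply(seq_len(k), function(i) {
    A <- random_hermitian(dim, field)
    A <- A / frob_norm(A)
    list(bi = block, bj = block, v = strength * stats::runif(1, 0.3, 1),
         Ai = A, Aj = A)
  })
}

#' Generate a single-type quadratic SCF model problem
#'
#' One particle type, one symmetry block, `f_max = 2` (spin-restricted
#' convention), `2 * n_occ_pairs` particles.  The core matrix `H` is a
#' random Hermitian with an enforced spectral gap after the `n_occ_pairs`-th
#' level; the two-body superoperator is a random PSD separable form scaled
#' by `strength`.  `strength = 0` gives a linear problem solved exactly by
#' one Roothaan step; large `strength` with a core-Hamiltonian guess makes
#' the first Roothaan step overshoot, which is the regime the optimal
#' damping algorithm is for.
#'
#' @param dim block dimension (>= 2)
#' @param n_occ_pairs number of doubly occupied orbitals at the Aufbau
#'   ground state (default 1)
#' @param strength two-body interaction scale (default 1)
#' @param field `"real"` or `"complex"`
#' @param seed integer seed; generation is fully deterministic given it
#' @param ensure_aufbau require the instance to have an Aufbau-representable
#'   ground state with a positive Fermi gap (default `TRUE`); instances
#'   failing the convex-relaxation check are regenerated from a
#'   deterministically derived seed.  Set `FALSE` when generating
#'   pathological hard-start cases on purpose.
#' @return a `model_problem`
#' @export
make_quadratic_problem <- function(dim, n_occ_pairs = 1, strength = 1,
                                   field = c("real", "complex"),
                                   seed = NULL, ensure_aufbau = TRUE) {
  field <- match.arg(field)
  stopifnot(dim >= 2, n_occ_pairs >= 1)
  if (2 * n_occ_pairs > 2 * dim) stop("infeasible occupation")
  for (attempt in 0:59) {
    if (!is.null(seed)) set.seed((seed + 7919L * attempt) %% .Machine$integer.max)
    ## core Hamiltonian with a spectral gap after level n_occ_pairs
    evals <- cumsum(stats::runif(dim, 0.2, 1.0))
    if (n_occ_pairs < dim) {
      evals[(n_occ_pairs + 1):dim] <- evals[(n_occ_pairs + 1):dim] + 1.0
    }
    evals <- evals - mean(evals) - 1
    U <- random_unitary(dim, field)
    H <- hermitize(U %*% (evals * ct(U)))
    terms <- if (strength > 0) intra_terms(1L, dim, field, strength)
             else list()
    specs <- list(block_spec(1L, dim, f_max = 2))
    problem <- new_model_problem(specs, n_particles = 2 * n_occ_pairs,
                                 H = list(H), terms = terms, field = field,
                                 seed = seed)
    if (!ensure_aufbau || aufbau_well_posed(problem)) return(problem)
  }
  stop("could not generate an Aufbau-well-posed instance; ",
       "lower `strength` or set ensure_aufbau = FALSE")
}

#' Generate a coupled two-species quadratic model problem
#'
#' Emulates the structure of coupled electron-proton SCF: two particle
#' types with their own repulsive-like (PSD) intra-type interactions, plus
#' an inter-type separable coupling whose sign is configurable (negative =
#' attractive, the physical electron-proton case).  Each inter-type weight
#' is capped below the smallest intra-type weight so the coupled functional
#' stays bounded below; construction additionally verifies boundedness by
#' sampling random feasible densities and checks the Fock derivative.
#'
#' @param dims length-2 integer vector of block dimensions
#' @param n_particles length-2 particle counts (type 1 has `f_max = 2`,
#'   type 2 `f_max = 1`, mirroring restricted electrons + high-spin protons)
#' @param intra_strengths length-2 intra-type interaction scales
#' @param inter_strength magnitude of the inter-type coupling
#' @param inter_sign +1 or -1 (default -1, attractive)
#' @param field `"real"` or `"complex"`
#' @param seed integer seed
#' @param ensure_aufbau as in [make_quadratic_problem()]
#' @return a `model_problem` with two blocks (one per type)
#' @export
make_two_species_problem <- function(dims = c(4L, 3L),
                                     n_particles = c(2, 1),
                                     intra_strengths = c(1, 1),
                                     inter_strength = 0.3,
                                     inter_sign = -1,
                                     field = c("real", "complex"),
                                     seed = NULL, ensure_aufbau = TRUE) {
  field <- match.arg(field)
  stopifnot(length(dims) == 2, length(n_particles) == 2,
            inter_sign %in% c(-1, 1))
  f_max <- c(2, 1)
  for (t in 1:2) {
    if (n_particles[t] > dims[t] * f_max[t]) stop("infeasible occupation")
  }
  for (attempt in 0:59) {
    if (!is.null(seed)) set.seed((seed + 7919L * attempt) %% .Machine$integer.max)
    specs <- list(block_spec(1L, dims[1], f_max = 2, block_label = "e"),
                  block_spec(2L, dims[2], f_max = 1, block_label = "p"))
    H <- lapply(1:2, function(t) {
      nocc <- max(1L, ceiling(n_particles[t] / f_max[t]))
      evals <- cumsum(stats::runif(dims[t], 0.2, 1.0))
      if (nocc < dims[t]) {
        evals[(nocc + 1):dims[t]] <- evals[(nocc + 1):dims[t]] + 1.0
      }
      evals <- evals - mean(evals) - 1
      U <- random_unitary(dims[t], field)
      hermitize(U %*% (evals * ct(U)))
    })
    terms <- c(intra_terms(1L, dims[1], field, intra_strengths[1]),
               intra_terms(2L, dims[2], field, intra_strengths[2]))
    min_intra <- min(vapply(terms, function(tm) abs(tm$v), numeric(1)))
    k_int <- min(dims)
    vcap <- 0.9 * min_intra
    inter <- lapply(seq_len(k_int), function(i) {
      Ai <- random_hermitian(dims[1], field); Ai <- Ai / frob_norm(Ai)
      Aj <- random_hermitian(dims[2], field); Aj <- Aj / frob_norm(Aj)
      v <- inter_sign * min(inter_strength * stats::runif(1, 0.3, 1), vcap)
      list(bi = 1L, bj = 2L, v = v, Ai = Ai, Aj = Aj)
    })
    problem <- new_model_problem(specs, n_particles, H, c(terms, inter),
                                 field, seed)
    chk <- sample_boundedness(problem, n = 200)
    if (!is.finite(chk$min_energy)) next
    if (!ensure_aufbau || aufbau_well_posed(problem)) return(problem)
  }
  stop("could not generate an Aufbau-well-posed instance; ",
       "lower the interaction strengths or set ensure_aufbau = FALSE")
}

#' Sample the boundedness of a model problem
#'
#' Evaluates the energy at random feasible densities (eigenvalues in
#' `[0, f_max]`, correct per-type traces) and at extreme Aufbau-like
#' fillings; returns the smallest energy seen.
#'
#' @param problem a `model_problem`
#' @param n number of random densities (default 1000)
#' @param seed optional seed for the sampling
#' @return list with `min_energy` and `max_energy`
#' @export
sample_boundedness <- function(problem, n = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  emin <- Inf; emax <- -Inf
  for (k in seq_len(n)) {
    P <- random_feasible_density(problem)
    E <- Re(model_energy(problem, P))
    emin <- min(emin, E); emax <- max(emax, E)
  }
  list(min_energy = emin, max_energy = emax)
}

#' Random feasible density matrices for a model problem
#'
#' Draws random occupations on the capped simplex of each particle type and
#' random natural orbitals.
#'
#' @param problem a `model_problem`
#' @return list of per-block Hermitian densities with correct type traces
#' @export
random_feasible_density <- function(problem) {
  specs <- problem$specs
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  P <- vector("list", length(specs))
  for (t in unique(types)) {
    blocks <- which(types == t)
    caps <- unlist(lapply(blocks, function(b) {
      rep(specs[[b]]$f_max, specs[[b]]$dim)
    }))
    raw <- stats::runif(length(caps), 0, max(caps))
    f <- project_capped_simplex(raw, caps, problem$n_particles[t])
    off <- 0
    for (b in blocks) {
      d <- specs[[b]]$dim
      U <- random_unitary(d, problem$field)
      P[[b]] <- hermitize(U %*% (f[(off + 1):(off + d)] * ct(U)))
      off <- off + d
    }
  }
  P
}

#' Euclidean projection onto a capped simplex
#'
#' Finds `f` minimizing `||f - v||` subject to `0 <= f_i <= cap_i` and
#' `sum(f) = total`, by bisecting the shift in
#' `f_i = clamp(v_i - mu, 0, cap_i)`.
#'
#' @param v numeric vector
#' @param cap per-entry upper bounds
#' @param total target sum (must satisfy `0 <= total <= sum(cap)`)
#' @return the projected vector
#' @export
project_capped_simplex <- function(v, cap, total) {
  stopifnot(length(v) == length(cap), total >= -1e-12,
            total <= sum(cap) + 1e-12)
  total <- min(max(total, 0), sum(cap))
  lo <- min(v - cap) - 1
  hi <- max(v) + 1
  ssum <- function(mu) sum(pmin(pmax(v - mu, 0), cap))
  for (k in 1:100) {
    mid <- (lo + hi) / 2
    if (ssum(mid) > total) lo <- mid else hi <- mid
  }
  f <- pmin(pmax(v - (lo + hi) / 2, 0), cap)
  ## exact trace: spread the (tiny) residual over the free entries
  free <- f > 1e-14 & f < cap - 1e-14
  resid <- total - sum(f)
  if (any(free)) f[free] <- f[free] + resid / sum(free)
  f
}

## Projection of concatenated natural occupations onto the *relaxed* capped
## trace simplex (eigenvalues clipped into [0, f_max], trace fixed).  Used
## for the convex-relaxation well-posedness check of the generators.
project_relaxed_density <- function(M_list, problem) {
  specs <- problem$specs
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  P <- vector("list", length(specs))
  for (t in unique(types)) {
    blocks <- which(types == t)
    eigs <- lapply(blocks, function(b) eigen(hermitize(M_list[[b]]),
                                             symmetric = TRUE))
    vals <- unlist(lapply(eigs, function(e) Re(e$values)))
    caps <- unlist(lapply(blocks, function(b) {
      rep(specs[[b]]$f_max, specs[[b]]$dim)
    }))
    f <- project_capped_simplex(vals, caps, problem$n_particles[t])
    off <- 0
    for (i in seq_along(blocks)) {
      b <- blocks[i]
      d <- specs[[b]]$dim
      U <- eigs[[i]]$vectors
      P[[b]] <- hermitize(U %*% (f[(off + 1):(off + d)] * ct(U)))
      off <- off + d
    }
  }
  P
}

## Retraction of Hermitian per-block matrices onto the idempotent-density
## manifold of each particle type: eigendecompose, then refill the natural
## occupations by greedy Aufbau over the concatenated spectra (largest
## eigenvalue first, up to each block's f_max, at most one fractional
## orbital) -- the extreme points of the capped trace simplex.  This is the
## set the Aufbau-based SCF iterates on, and the set the brute-force oracle
## must search.
project_feasible_density <- function(M_list, problem) {
  specs <- problem$specs
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  P <- vector("list", length(specs))
  for (t in unique(types)) {
    blocks <- which(types == t)
    eigs <- lapply(blocks, function(b) eigen(hermitize(M_list[[b]]),
                                             symmetric = TRUE))
    vals <- unlist(lapply(eigs, function(e) Re(e$values)))
    caps <- unlist(lapply(blocks, function(b) {
      rep(specs[[b]]$f_max, specs[[b]]$dim)
    }))
    f <- numeric(length(vals))
    remaining <- problem$n_particles[t]
    for (k in order(vals, decreasing = TRUE)) {
      if (remaining <= 0) break
      f[k] <- min(caps[k], remaining)
      remaining <- remaining - f[k]
    }
    off <- 0
    for (i in seq_along(blocks)) {
      b <- blocks[i]
      d <- specs[[b]]$dim
      U <- eigs[[i]]$vectors
      P[[b]] <- hermitize(U %*% (f[(off + 1):(off + d)] * ct(U)))
      off <- off + d
    }
  }
  P
}

#' Brute-force reference minimum of a model problem
#'
#' Independent oracle for the SCF solvers.  For a real single-block
#' dimension-2 problem whose particle count fills exactly one orbital, the
#' occupied subspace is parametrized by one rotation angle and scanned
#' densely (grid `1e-4` rad) followed by local refinement.  In all other
#' cases, projected-gradient descent on the feasible density set (eigenvalue
#' projection onto the capped simplex, backtracking step control) is run
#' from `n_restarts` random feasible starts plus the Aufbau filling of the
#' core Hamiltonian, and the best minimum found is returned.
#'
#' @param problem a `model_problem`
#' @param n_restarts number of random restarts for the descent (default 100)
#' @param max_iter iteration cap per descent (default 400)
#' @param seed optional seed for the restarts
#' @return list with `E_min`, `P_min` (per-block densities), and
#'   `grad_norm` (max commutator norm at the minimum)
#' @export
brute_force_reference <- function(problem, n_restarts = 100, max_iter = 400,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  specs <- problem$specs
  scan_ok <- length(specs) == 1 && problem$field == "real" &&
    specs[[1]]$dim == 2 &&
    abs(problem$n_particles[1] - specs[[1]]$f_max) < 1e-12
  best <- NULL
  if (scan_ok) {
    fmax <- specs[[1]]$f_max
    evalE <- function(th) {
      v <- c(cos(th), sin(th))
      Re(model_energy(problem, list(fmax * tcrossprod(v))))
    }
    th <- seq(0, pi, by = 1e-4)
    Es <- vapply(th, evalE, numeric(1))
    k <- which.min(Es)
    opt <- stats::optimize(evalE, c(th[max(1, k - 1)], th[min(length(th), k + 1)]),
                           tol = 1e-12)
    v <- c(cos(opt$minimum), sin(opt$minimum))
    best <- list(E_min = opt$objective, P_min = list(fmax * tcrossprod(v)))
  }
  starts <- c(list(aufbau_core_density(problem)),
              lapply(seq_len(n_restarts), function(i) {
                random_feasible_density(problem)
              }))
  for (P0 in starts) {
    res <- pg_descent(problem, P0, max_iter = max_iter)
    if (is.null(best) || res$E < best$E_min) {
      best <- list(E_min = res$E, P_min = res$P)
    }
  }
  Fb <- model_fock(problem, best$P_min)
  errs <- lapply(seq_along(Fb), function(b) {
    commutator_error(Fb[[b]], best$P_min[[b]])
  })
  best$grad_norm <- error_norm(errs, "max")
  best
}

## Aufbau density of the core Hamiltonian (the "core guess").
aufbau_core_density <- function(problem) {
  specs <- problem$specs
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  eigs <- lapply(problem$H, eigen_ascending)
  P <- vector("list", length(specs))
  for (t in unique(types)) {
    blocks <- which(types == t)
    f <- aufbau_fill(lapply(blocks, function(b) eigs[[b]]$values),
                     vapply(blocks, function(b) specs[[b]]$f_max, numeric(1)),
                     problem$n_particles[t])
    for (i in seq_along(blocks)) {
      b <- blocks[i]
      P[[b]] <- build_density(list(C = eigs[[b]]$vectors, f = f[[i]]))
    }
  }
  P
}

## Aufbau well-posedness check.  Minimizes the energy over the *relaxed*
## feasible set (a convex superset of the idempotent manifold) by projected
## gradient from the core guess plus a couple of random restarts, then
## requires (a) the relaxed minimizer to be reproduced by Aufbau filling of
## its own Fock matrix and (b) a positive Fermi gap in every particle type.
## Instances failing the check have degenerate/fractional ground-state
## occupations, which Aufbau-based SCF cannot represent (explicitly outside
## the optimizer's scope).
aufbau_well_posed <- function(problem, gap_min = 1e-2, n_restarts = 2) {
  starts <- c(list(aufbau_core_density(problem)),
              lapply(seq_len(n_restarts), function(i) {
                random_feasible_density(problem)
              }))
  best <- NULL
  for (P0 in starts) {
    res <- pg_descent(problem, P0, max_iter = 300, projection = "relaxed")
    if (is.null(best) || res$E < best$E) best <- res
  }
  F <- model_fock(problem, best$P)
  specs <- problem$specs
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  eigs <- lapply(F, eigen_ascending)
  ok <- TRUE
  for (t in unique(types)) {
    blocks <- which(types == t)
    vals <- sort(unlist(lapply(blocks, function(b) eigs[[b]]$values)))
    f <- aufbau_fill(lapply(blocks, function(b) eigs[[b]]$values),
                     vapply(blocks, function(b) specs[[b]]$f_max, numeric(1)),
                     problem$n_particles[t])
    nfill <- sum(unlist(f) > 1e-8)
    if (nfill >= 1 && nfill < length(vals)) {
      if (vals[nfill + 1] - vals[nfill] < gap_min) ok <- FALSE
    }
    ## the Aufbau density of F(P*) must reproduce P*
    for (i in seq_along(blocks)) {
      b <- blocks[i]
      Pa <- build_density(list(C = eigs[[b]]$vectors, f = f[[i]]))
      if (frob_norm(Pa - best$P[[b]]) > 1e-3 * (1 + frob_norm(best$P[[b]]))) {
        ok <- FALSE
      }
    }
  }
  ok
}

## One projected-gradient descent with backtracking.
pg_descent <- function(problem, P0, max_iter = 400, tol = 1e-13,
                       projection = c("idempotent", "relaxed")) {
  projection <- match.arg(projection)
  proj <- if (projection == "idempotent") project_feasible_density
          else project_relaxed_density
  P <- P0
  E <- Re(model_energy(problem, P))
  eta <- 0.5
  stall <- 0L
  for (it in seq_len(max_iter)) {
    F <- model_fock(problem, P)
    accepted <- FALSE
    for (bt in 1:40) {
      M <- lapply(seq_along(P), function(b) P[[b]] - eta * F[[b]])
      Pn <- proj(M, problem)
      En <- Re(model_energy(problem, Pn))
      if (En <= E + 1e-14 * (abs(E) + 1)) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break
    dE <- E - En
    P <- Pn; E <- En
    eta <- min(eta * 1.4, 1e3)
    if (dE < tol * (abs(E) + 1)) {
      stall <- stall + 1L
      if (stall >= 3L) break
    } else stall <- 0L
  }
  list(E = E, P = P, iterations = it)
}

#' Finite-difference check of the Fock derivative
#'
#' Verifies `dE/dh E(P + h D) = Re<F(P), D>` for random Hermitian
#' directions by central differences.
#'
#' @param problem a `model_problem`
#' @param n_directions number of random directions (default 5)
#' @param h step size (default `1e-5`)
#' @param seed optional seed
#' @return maximal absolute deviation over the tested directions
#' @export
check_fock_derivative <- function(problem, n_directions = 5, h = 1e-5,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- random_feasible_density(problem)
  F <- model_fock(problem, P)
  worst <- 0
  for (k in seq_len(n_directions)) {
    D <- lapply(problem$specs, function(s) {
      A <- random_hermitian(s$dim, problem$field)
      A / frob_norm(A)
    })
    Pp <- mapply(function(P, D) P + h * D, P, D, SIMPLIFY = FALSE)
    Pm <- mapply(function(P, D) P - h * D, P, D, SIMPLIFY = FALSE)
    num <- (Re(model_energy(problem, Pp)) - Re(model_energy(problem, Pm))) /
      (2 * h)
    ana <- sum(vapply(seq_along(F), function(b) {
      Re(tr_prod(F[[b]], D[[b]]))
    }, numeric(1)))
    worst <- max(worst, abs(num - ana))
  }
  worst
}

#' Serialize a model problem to JSON
#'
#' Plain-text regression-fixture format: matrices are stored as `re`/`im`
#' component lists with dimensions; fully round-trips through
#' [problem_from_json()].
#'
#' @param problem a `model_problem`
#' @param path file path to write
#' @return `path`, invisibly
#' @export
problem_to_json <- function(problem, path) {
  mat_enc <- function(M) {
    list(n = nrow(M), re = as.numeric(Re(M)), im = as.numeric(Im(M)))
  }
  obj <- list(
    field = problem$field,
    n_particles = problem$n_particles,
    specs = lapply(problem$specs, function(s) {
      list(particle_type = s$particle_type, block_label = s$block_label,
           dim = s$dim, f_max = s$f_max)
    }),
    H = lapply(problem$H, mat_enc),
    terms = lapply(problem$terms, function(tm) {
      list(bi = tm$bi, bj = tm$bj, v = tm$v,
           Ai = mat_enc(tm$Ai), Aj = mat_enc(tm$Aj))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model problem from JSON
#' @param path file written by [problem_to_json()]
#' @return a `model_problem`
#' @export
problem_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec <- function(m) {
    n <- m$n
    re <- as.numeric(unlist(m$re))
    im <- as.numeric(unlist(m$im))
    M <- matrix(re, n, n)
    if (any(im != 0)) M <- M + 1i * matrix(im, n, n)
    M
  }
  specs <- lapply(obj$specs, function(s) {
    block_spec(s$particle_type, s$dim, s$f_max, s$block_label)
  })
  H <- lapply(obj$H, dec)
  terms <- lapply(obj$terms, function(tm) {
    list(bi = as.integer(tm$bi), bj = as.integer(tm$bj), v = as.numeric(tm$v),
         Ai = dec(tm$Ai), Aj = dec(tm$Aj))
  })
  new_model_problem(specs, as.numeric(unlist(obj$n_particles)), H, terms,
                    obj$field, NA_integer_)
}
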