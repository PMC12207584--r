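## Optimal damping.  When the orbital gradient is huge (poor guess, e.g. a
## core-Hamiltonian start) even EDIIS/ADIIS can fail; the optimal damping
## algorithm relaxes the density along the convex segment between the best
## density so far, P0, and the Aufbau density P1 of the orbitals that
## diagonalize F(P0).  Energies and exact endpoint gradients afford a cubic
## fit for the mixing factor; multiple particle types get a per-type mixing
## direction obtained by projecting the negative gradient into the unit box.

#' Interior minimum of a cubic fit from endpoint values and slopes
#'
#' Fits the unique cubic with `E(0) = E0`, `E'(0) = dE0`, `E(1) = E1`,
#' `E'(1) = dE1` and returns the interior local minimum in `(0, 1)`; when
#' the fit degenerates to a quadratic/linear the corresponding stationary
#' point is used.  If several interior minima exist, the one with the lower
#' fitted value wins.  Returns `NULL` when the fit has no interior minimum
#' (monotone fits).
#'
#' @param E0,dE0,E1,dE1 finite reals: endpoint energies and slopes
#' @return scalar `lambda*` in (0, 1), or `NULL`
#' @export
cubic_line_minimum <- function(E0, dE0, E1, dE1) {
  stopifnot(is.finite(E0), is.finite(dE0), is.finite(E1), is.finite(dE1))
  ## E(x) = a x^3 + b x^2 + c x + d
  d <- E0
  c3 <- dE0
  a <- dE0 + dE1 - 2 * (E1 - E0)
  b <- 3 * (E1 - E0) - 2 * dE0 - dE1
  evalc <- function(x) ((a * x + b) * x + c3) * x + d
  scale <- max(abs(a), abs(b), abs(c3), 1)
  cands <- numeric(0)
  if (abs(a) > 1e-14 * scale) {
    disc <- 4 * b^2 - 12 * a * c3
    if (disc >= 0) {
      r <- (-2 * b + c(1, -1) * sqrt(disc)) / (6 * a)
      ## keep roots that are local minima: E''(x) = 6 a x + 2 b > 0
      cands <- r[6 * a * r + 2 * b > 0]
    }
  } else if (abs(b) > 1e-14 * scale) {
    if (b > 0) cands <- -c3 / (2 * b)
  }
  cands <- cands[is.finite(cands) & cands > 0 & cands < 1]
  if (length(cands) == 0L) return(NULL)
  cands[which.min(vapply(cands, evalc, numeric(1)))]
}

#' Per-type mixing direction from energy gradients
#'
#' Given the gradients `g_sigma = Tr F0^sigma (P1^sigma - P0^sigma)` of the
#' energy with respect to the per-type mixing factors, the components of the
#' search direction are `s_i = max(0, -g_i)` (clipping keeps the step inside
#' the unit box) and the trial mixing vector steps to the boundary:
#' `lambda_trial = s / max_i s_i`.
#'
#' @param gradients numeric vector of per-type gradients
#' @return numeric vector in `[0, 1]` with maximal component 1, or `NULL`
#'   when every gradient is nonnegative (no descent direction)
#' @export
mixing_direction <- function(gradients) {
  s <- pmax(0, -gradients)
  if (all(s == 0)) return(NULL)
  s / max(s)
}

#' Natural-orbital block state of a (mixed) density matrix
#'
#' Eigendecomposes `P` into natural orbitals and occupations, clamps tiny
#' negative occupations to zero, caps at `f_max`, and rescales to conserve
#' the trace.  Orbital "energies" are taken as expectation values of the
#' supplied Fock matrix and the orbitals re-sorted ascending in them, so
#' downstream Aufbau bookkeeping stays consistent.
#'
#' @param P Hermitian density matrix
#' @param F0 Hermitian matrix supplying orbital-energy expectation values
#' @param f_max maximal orbital occupation of the block
#' @return a [block_state()]
#' @export
natural_orbital_state <- function(P, F0, f_max) {
  e <- eigen(hermitize(P), symmetric = TRUE)
  f <- Re(e$values)
  target <- sum(f)
  f[f < 0] <- 0
  f[f > f_max] <- f_max
  if (sum(f) > 0 && abs(sum(f) - target) > 0) f <- f * (target / sum(f))
  C <- e$vectors
  eps <- Re(diag(ct(C) %*% F0 %*% C))
  ord <- order(eps)
  block_state(C[, ord, drop = FALSE], eps[ord], f[ord], validate = FALSE)
}

## Per-particle-type mixing gradients g_sigma = Re Tr F0 (P1 - P0),
## accumulated over the blocks of each type.
oda_gradients <- function(best, candidate, specs) {
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  g <- numeric(max(types))
  for (b in seq_along(specs)) {
    g[types[b]] <- g[types[b]] +
      Re(tr_prod(best$F[[b]], candidate$P[[b]] - best$P[[b]]))
  }
  g
}

## Build the per-block mixed density (1 - lam_type) P0 + lam_type P1.
oda_mix_density <- function(best, candidate, lam_type, specs) {
  lapply(seq_along(specs), function(b) {
    lam <- lam_type[specs[[b]]$particle_type]
    (1 - lam) * best$P[[b]] + lam * candidate$P[[b]]
  })
}

#' One optimal-damping relaxation step
#'
#' `best` is the lowest-energy entry in the history; `candidate` is the
#' already-evaluated entry built from the orbitals that diagonalize the best
#' entry's Fock matrices (a Roothaan step from the best entry).  If the
#' candidate lowered the energy it is accepted outright.  Otherwise the
#' per-type mixing direction is computed, the energy is evaluated at the
#' boundary trial point, a cubic is fitted along the segment from the
#' endpoint energies and exact gradients, and the state at the fitted
#' minimum (natural orbitals of the mixed density) is evaluated once.  When
#' the cubic offers no interior minimum the mixing factor is bisected (at
#' most `max_bisect` times) until the energy drops, keeping the best point
#' found.
#'
#' @param best lowest-energy [iteration_entry()]
#' @param candidate [iteration_entry()] from a Roothaan step off `best`
#' @param specs list of [block_spec()]
#' @param eval_state function `(states, label) -> iteration_entry` that
#'   evaluates the Fock functional at given block states (the driver passes
#'   a recording wrapper so every evaluation lands in the history and trace)
#' @param max_bisect maximal number of bisections (default 5)
#' @return the final [iteration_entry()] produced by the step
#' @export
oda_relax <- function(best, candidate, specs, eval_state, max_bisect = 5L) {
  E0 <- best$E_total
  if (candidate$E_total < E0) return(candidate)

  g <- oda_gradients(best, candidate, specs)
  lam_dir <- mixing_direction(g)
  if (is.null(lam_dir)) {
    ## no descent direction: P1 coincides with P0 (Aufbau minimizes
    ## Tr F0 P, so g <= 0 with equality only at a fixed point)
    return(candidate)
  }

  n_types <- length(g)
  single <- all(lam_dir == 1)
  mixed_entry <- function(s) {
    lam <- s * lam_dir
    Pmix <- oda_mix_density(best, candidate, lam, specs)
    states <- lapply(seq_along(specs), function(b) {
      natural_orbital_state(Pmix[[b]], best$F[[b]], specs[[b]]$f_max)
    })
    eval_state(states, "oda")
  }

  ## endpoint s = 1 of the direction: for a single type this is exactly the
  ## candidate (already evaluated); otherwise evaluate the boundary point
  if (single) {
    trial <- candidate
  } else {
    trial <- mixed_entry(1)
    if (trial$E_total < E0) return(trial)
  }
  dE0 <- sum(lam_dir * g)
  gt <- oda_gradients(list(F = trial$F, P = best$P), candidate, specs)
  dE1 <- sum(lam_dir * gt)
  lam_star <- cubic_line_minimum(E0, dE0, trial$E_total, dE1)
  if (!is.null(lam_star)) {
    return(mixed_entry(lam_star))
  }
  ## cubic found no interior minimum although the endpoint went uphill:
  ## bisect toward the best entry
  s <- 0.5
  out <- trial
  for (k in seq_len(max_bisect)) {
    out <- mixed_entry(s)
    if (out$E_total < E0) break
    s <- s / 2
  }
  out
}
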