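## Independent oracles and small fixture builders shared across test files.
## Oracles deliberately take different computational routes than the package
## code they check.

## Equality-constrained least squares: minimize c^T B c subject to
## sum(c) = 1, by eliminating the constraint (c = e_m + Z y with
## Z = [I; -1^T]) and solving the reduced normal equations.  Independent of
## the bordered-system route used by diis_weights_from_b().
oracle_constrained_ls <- function(B) {
  m <- nrow(B)
  if (m == 1L) return(1)
  Z <- rbind(diag(m - 1), rep(-1, m - 1))
  a <- c(rep(0, m - 1), 1)
  y <- solve(t(Z) %*% B %*% Z, -t(Z) %*% B %*% a)
  as.numeric(a + Z %*% y)
}

## Random symmetric positive-definite matrix with a prescribed condition
## number ceiling (eigenvalues log-uniform over at most `decades` decades).
random_spd <- function(m, decades = 6) {
  lam <- 10^stats::runif(m, 0, decades)
  Q <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
  Q %*% (lam * t(Q))
}

## Brute-force Aufbau oracle: enumerate every integer filling of the
## orbitals (occupations 0..f_max per orbital) with the correct particle
## count and return the minimal total one-particle energy sum(f * eps).
oracle_aufbau_energy <- function(orbital_energies, f_max, n_particles) {
  eps <- unlist(orbital_energies)
  caps <- rep(f_max, lengths(orbital_energies))
  grids <- lapply(caps, function(k) 0:k)
  G <- as.matrix(do.call(expand.grid, grids))
  G <- G[rowSums(G) == n_particles, , drop = FALSE]
  min(G %*% eps)
}

## Minimal stub iteration entries for history-policy tests: one 1x1 block
## whose density value doubles as the "distance coordinate".
stub_entry <- function(E, it, p = 0) {
  st <- block_state(matrix(1, 1, 1), 0, 1, validate = FALSE)
  iteration_entry(list(st), F = list(matrix(0, 1, 1)),
                  P = list(matrix(p, 1, 1)), E_total = E,
                  err = list(matrix(0, 1, 1)), iteration_index = it,
                  validate = FALSE)
}

## Evaluate a model problem at explicit block states and wrap the result as
## an iteration entry (used to drive oda_relax() outside the SCF loop).
entry_from_states <- function(problem, states, it = 1L) {
  ev <- model_evaluator(problem)
  C <- lapply(states, `[[`, "C")
  f <- lapply(states, `[[`, "f")
  out <- ev(C, f)
  P <- lapply(states, build_density)
  err <- mapply(commutator_error, out$F, P, SIMPLIFY = FALSE)
  iteration_entry(states, out$F, P, out$E_total, err, it, validate = FALSE)
}

## Core-guess entry (states from diagonalizing H) of a model problem.
core_entry <- function(problem, it = 1L) {
  states <- roothaan_update(problem$H, problem$specs, problem$n_particles)
  entry_from_states(problem, states, it)
}

## Random point on the unit simplex.
random_simplex_point <- function(m) {
  x <- stats::rexp(m)
  x / sum(x)
}

## Random history of feasible densities with their model energies and Fock
## matrices, in the (energies, F_list, P_list) layout the EDIIS/ADIIS
## builders consume.
random_model_history <- function(problem, m) {
  P_list <- lapply(seq_len(m), function(i) random_feasible_density(problem))
  F_list <- lapply(P_list, function(P) model_fock(problem, P))
  energies <- vapply(P_list, function(P) Re(model_energy(problem, P)),
                     numeric(1))
  list(energies = energies, F_list = F_list, P_list = P_list)
}
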