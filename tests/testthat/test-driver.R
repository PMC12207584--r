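test_that("roothaan_update diagonalizes and refills by Aufbau", {
  specs <- list(block_spec(1, 2, f_max = 2))
  st <- roothaan_update(list(diag(c(2, 1))), specs, n_particles = 2)
  expect_equal(st[[1]]$E_orb, c(1, 2))
  expect_equal(abs(st[[1]]$C), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(st[[1]]$f, c(2, 0))
  ## already-diagonal ascending F: identity orbitals up to phase
  st2 <- roothaan_update(list(diag(c(-1, 3))), specs, 2)
  expect_equal(abs(st2[[1]]$C), diag(2))
  ## random Hermitian: C^H F C diagonal, ascending
  set.seed(71)
  for (field in c("real", "complex")) {
    F <- scfaccel:::random_hermitian(5, field)
    s <- roothaan_update(list(F), list(block_spec(1, 5, 2)), 2)[[1]]
    D <- Conj(t(s$C)) %*% F %*% s$C
    expect_equal(D, diag(s$E_orb) + 0 * D, tolerance = 1e-10)
    expect_false(is.unsorted(s$E_orb))
  }
})

test_that("hybrid weights interpolate linearly between the regimes", {
  c_diis <- c(0.9, 0.1)
  c_int <- c(0.2, 0.8)
  expect_equal(hybrid_weights(1e-5, c_diis, c_int), c_diis)
  expect_equal(hybrid_weights(0.5, c_diis, c_int), c_int)
  mid <- hybrid_weights((1e-4 + 1e-1) / 2, c_diis, c_int)
  expect_equal(mid, (c_diis + c_int) / 2, tolerance = 1e-12)
  expect_equal(sum(mid), 1)
  expect_equal(hybrid_interpolation_factor(1e-1), 0)
  expect_equal(hybrid_interpolation_factor(1e-4), 1)
})

test_that("extrapolate_fock mixes per-block matrices", {
  F1 <- list(diag(c(1, 2)))
  expect_equal(extrapolate_fock(list(F1), 1), F1)
  F2 <- list(-diag(c(1, 2)))
  expect_equal(extrapolate_fock(list(F1, F2), c(0.5, 0.5)),
               list(matrix(0, 2, 2)))
  ## DIIS-weighted combinations stay Hermitian
  set.seed(73)
  hist_F <- lapply(1:4, function(i) {
    list(scfaccel:::random_hermitian(3, "complex"))
  })
  errs <- lapply(1:4, function(i) {
    list(commutator_error(hist_F[[i]][[1]],
                          scfaccel:::random_hermitian(3, "complex")))
  })
  w <- diis_weights(errs, d = 0)
  Fbar <- extrapolate_fock(hist_F, w)[[1]]
  expect_equal(Fbar, Conj(t(Fbar)), tolerance = 1e-12)
})

test_that("solve_scf converges a quadratic model to its brute-force minimum", {
  p <- make_quadratic_problem(4, 1, strength = 1, seed = 501)
  res <- solve_scf(p)
  expect_true(res$converged)
  expect_lt(error_norm(res$final$err, "rms"), 1e-7)
  ref <- brute_force_reference(p, n_restarts = 30, seed = 502)
  expect_equal(res$final$E_total, ref$E_min, tolerance = 1e-8)
  ## at convergence the occupations satisfy Aufbau in the final orbital
  ## energies: occupied below virtual
  s <- res$final$states[[1]]
  expect_lte(max(s$E_orb[s$f > 1e-6]), min(s$E_orb[s$f < 1e-6]))
})

test_that("an exact-solution guess converges in one iteration", {
  p <- make_quadratic_problem(4, 1, strength = 1, seed = 503)
  res <- solve_scf(p)
  res2 <- solve_scf(p, guess = res$final$states)
  expect_true(res2$converged)
  expect_equal(res2$n_iterations, 1L)
  expect_equal(res2$trace$strategy, "guess")
})

test_that("complex-Hermitian problems converge with real energies", {
  p <- make_quadratic_problem(4, 1, strength = 1, field = "complex",
                              seed = 505)
  res <- solve_scf(p)
  expect_true(res$converged)
  E <- model_energy(p, res$final$P)
  expect_lt(abs(Im(E)), 1e-10)
  expect_equal(Re(E), res$final$E_total, tolerance = 1e-10)
})

test_that("the best-energy trace column is non-increasing for every strategy", {
  for (seed in 507:509) {
    p <- make_quadratic_problem(5, 2, strength = 2, seed = seed)
    for (strat in c("diis", "hybrid", "full")) {
      res <- solve_scf(p, config = scf_config(strategy = strat,
                                              max_iterations = 60))
      expect_true(all(diff(res$trace$E_best) <= 1e-12),
                  label = sprintf("monotone best energy (%s, seed %d)",
                                  strat, seed))
      ## the reported final entry is the best energy ever seen
      expect_equal(res$final$E_total, min(res$trace$E_total))
    }
  }
})

test_that("non-convergence returns the best entry with converged = FALSE", {
  p <- make_quadratic_problem(4, 1, strength = 2, seed = 511)
  res <- solve_scf(p, config = scf_config(max_iterations = 3))
  expect_false(res$converged)
  expect_equal(res$n_iterations, 3L)
  expect_equal(res$final$E_total, min(res$trace$E_total))
})

test_that("the evaluator contract is enforced", {
  specs <- list(block_spec(1, 2, 2))
  bad <- scf_problem(specs, 2, function(C, f) {
    list(E_total = NaN, F = list(diag(2)))
  })
  expect_error(solve_scf(bad, guess = list(F = list(diag(2)))), "non-finite")
  expect_error(solve_scf(scf_problem(specs, 2, function(C, f) {
    list(E_total = 0, F = list(matrix(c(0, 1, 0, 0), 2, 2)))
  }), guess = list(F = list(diag(2)))), "Hermiticity")
})

test_that("stepwise and simultaneous solvers agree on coupled problems", {
  p <- make_two_species_problem(dims = c(4L, 3L), inter_strength = 0.3,
                                seed = 513)
  sim <- solve_scf(p)
  stw <- solve_stepwise(p)
  expect_true(sim$converged)
  expect_true(stw$converged)
  expect_lt(abs(sim$final$E_total - stw$final$E_total), 1e-7)
})

test_that("decoupled species converge in one effective macroiteration", {
  p <- make_two_species_problem(dims = c(3L, 3L), inter_strength = 0,
                                seed = 515)
  stw <- solve_stepwise(p)
  expect_true(stw$converged)
  expect_equal(stw$n_macro_effective, 1L)
  ## decoupled: joint minimum equals the stepwise one exactly
  sim <- solve_scf(p)
  expect_equal(stw$final$E_total, sim$final$E_total, tolerance = 1e-9)
})

test_that("a frozen group already at its optimum sub-solves in one iteration", {
  p <- make_two_species_problem(dims = c(3L, 3L), inter_strength = 0.2,
                                seed = 517)
  res <- solve_scf(p)
  states <- res$final$states
  sub <- scfaccel:::freeze_problem(as_scf_problem(p), states, blocks = 1L)
  subres <- solve_scf(sub, guess = states[1L])
  expect_true(subres$converged)
  expect_equal(subres$n_iterations, 1L)
})

test_that("tit-for-tat stagnation fallback hands control to optimal damping", {
  ## a problem DIIS alone struggles with: strong coupling, small history
  p <- make_quadratic_problem(5, 2, strength = 6, seed = 519)
  cfg <- scf_config(strategy = "full", history_capacity = 4,
                    oda_threshold = 1e6,   # only reachable via stagnation
                    max_iterations = 80)
  res <- solve_scf(p, config = cfg)
  expect_true(all(diff(res$trace$E_best) <= 1e-12))
  ## if stagnation ever fired, oda rows must appear in the trace
  if (!res$converged || res$n_iterations > 40) {
    expect_true(any(res$trace$strategy == "oda"))
  }
})
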