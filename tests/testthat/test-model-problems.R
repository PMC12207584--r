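test_that("generated problems have exact Fock derivatives", {
  for (field in c("real", "complex")) {
    p <- make_quadratic_problem(4, 1, strength = 2, field = field, seed = 601)
    expect_lt(check_fock_derivative(p, seed = 602), 1e-8)
  }
  p2 <- make_two_species_problem(seed = 603)
  expect_lt(check_fock_derivative(p2, seed = 604), 1e-8)
})

test_that("generators are seed-deterministic", {
  a <- make_quadratic_problem(4, 1, strength = 1.5, seed = 605)
  b <- make_quadratic_problem(4, 1, strength = 1.5, seed = 605)
  expect_identical(a$H, b$H)
  expect_identical(a$terms, b$terms)
  c2 <- make_two_species_problem(seed = 606)
  d2 <- make_two_species_problem(seed = 606)
  expect_identical(c2$terms, d2$terms)
})

test_that("every generated problem is bounded below on the feasible set", {
  for (seed in 607:609) {
    p <- make_quadratic_problem(4, 1, strength = 3, seed = seed)
    s <- sample_boundedness(p, n = 300, seed = seed)
    expect_true(is.finite(s$min_energy))
    expect_true(is.finite(s$max_energy))
  }
  p2 <- make_two_species_problem(inter_strength = 0.5, seed = 610)
  s2 <- sample_boundedness(p2, n = 300, seed = 611)
  expect_true(is.finite(s2$min_energy))
})

test_that("strength = 0 problems are solved exactly by one Roothaan step", {
  p <- make_quadratic_problem(4, 2, strength = 0, seed = 613)
  e <- scfaccel:::eigen_ascending(p$H[[1]])
  E_exact <- 2 * sum(e$values[1:2])
  res <- solve_scf(p)
  expect_true(res$converged)
  expect_equal(res$trace$E_total[1], E_exact, tolerance = 1e-12)
  ref <- brute_force_reference(p, n_restarts = 10, seed = 614)
  expect_equal(ref$E_min, E_exact, tolerance = 1e-9)
})

test_that("angle-scan and projected-gradient oracles agree in dimension 2", {
  for (seed in 615:617) {
    p <- make_quadratic_problem(2, 1, strength = 1.5, seed = seed)
    ref <- brute_force_reference(p, n_restarts = 25, seed = seed + 50)
    ## redo the scan by hand, independently of brute_force_reference
    evalE <- function(th) {
      v <- c(cos(th), sin(th))
      Re(model_energy(p, list(2 * tcrossprod(v))))
    }
    th <- seq(0, pi, length.out = 20001)
    Es <- vapply(th, evalE, numeric(1))
    k <- which.min(Es)
    lo <- th[max(1, k - 2)]; hi <- th[min(length(th), k + 2)]
    opt <- stats::optimize(evalE, c(lo, hi), tol = 1e-12)
    expect_equal(ref$E_min, opt$objective, tolerance = 1e-8)
  }
})

test_that("the reference minimum dominates every SCF iterate", {
  p <- make_quadratic_problem(5, 2, strength = 2, seed = 619)
  ref <- brute_force_reference(p, n_restarts = 40, seed = 620)
  res <- solve_scf(p)
  expect_true(all(res$trace$E_total >= ref$E_min - 1e-8))
  expect_lt(ref$grad_norm, 1e-5)
})

test_that("zero inter-species coupling separates into independent minima", {
  p <- make_two_species_problem(dims = c(3L, 3L), inter_strength = 0,
                                seed = 621)
  ref <- brute_force_reference(p, n_restarts = 30, seed = 622)
  ## independent single-type problems built from the same blocks
  sub <- function(b, t) {
    scfaccel:::new_model_problem(
      specs = list(block_spec(1L, p$specs[[b]]$dim, p$specs[[b]]$f_max)),
      n_particles = p$n_particles[t],
      H = p$H[b],
      terms = lapply(Filter(function(tm) tm$bi == b && tm$bj == b, p$terms),
                     function(tm) { tm$bi <- 1L; tm$bj <- 1L; tm }),
      field = p$field, seed = NA_integer_)
  }
  r1 <- brute_force_reference(sub(1, 1), n_restarts = 30, seed = 623)
  r2 <- brute_force_reference(sub(2, 2), n_restarts = 30, seed = 624)
  expect_equal(ref$E_min, r1$E_min + r2$E_min, tolerance = 1e-7)
})

test_that("relabeling the two species leaves the optimal energy invariant", {
  p <- make_two_species_problem(dims = c(3L, 3L), inter_strength = 0.4,
                                seed = 625)
  swap <- scfaccel:::new_model_problem(
    specs = list(block_spec(1L, p$specs[[2]]$dim, p$specs[[2]]$f_max),
                 block_spec(2L, p$specs[[1]]$dim, p$specs[[1]]$f_max)),
    n_particles = rev(p$n_particles),
    H = p$H[c(2, 1)],
    terms = lapply(p$terms, function(tm) {
      new <- tm
      new$bi <- c(2L, 1L)[tm$bi]
      new$bj <- c(2L, 1L)[tm$bj]
      new
    }),
    field = p$field, seed = NA_integer_)
  r1 <- brute_force_reference(p, n_restarts = 30, seed = 626)
  r2 <- brute_force_reference(swap, n_restarts = 30, seed = 627)
  expect_equal(r1$E_min, r2$E_min, tolerance = 1e-7)
})

test_that("model problems round-trip through the JSON fixture format", {
  for (field in c("real", "complex")) {
    p <- make_two_species_problem(field = field, seed = 629)
    path <- tempfile(fileext = ".json")
    problem_to_json(p, path)
    q <- problem_from_json(path)
    set.seed(630)
    P <- random_feasible_density(p)
    expect_equal(model_energy(q, P), model_energy(p, P), tolerance = 1e-12)
    expect_equal(model_fock(q, P), model_fock(p, P), tolerance = 1e-12)
    unlink(path)
  }
})

test_that("infeasible occupations are rejected", {
  expect_error(make_quadratic_problem(2, 3, seed = 1), "infeasible")
  expect_error(make_two_species_problem(dims = c(2L, 2L),
                                        n_particles = c(10, 1), seed = 1),
               "infeasible")
})
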