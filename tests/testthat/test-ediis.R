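test_that("minimize_on_simplex handles the closed-form cases", {
  ## f = c1^2 + c2^2 on the simplex: minimum at the centroid
  q <- simplex_quadratic(2 * diag(2), c(0, 0))
  x <- minimize_on_simplex(q)
  expect_equal(x, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(eval_simplex_quadratic(q, x), 0.5, tolerance = 1e-10)
  ## linear objective: vertex solution
  expect_equal(minimize_on_simplex(simplex_quadratic(matrix(0, 2, 2),
                                                     c(-2, 0))),
               c(1, 0), tolerance = 1e-12)
  ## symmetric m = 3 case
  expect_equal(minimize_on_simplex(simplex_quadratic(2 * diag(3),
                                                     numeric(3))),
               rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(minimize_on_simplex(simplex_quadratic(matrix(5, 1, 1), 2)), 1)
  expect_error(minimize_on_simplex(simplex_quadratic(matrix(NaN, 1, 1), 1)),
               "non-finite")
})

test_that("minimize_on_simplex stays feasible and beats the grid oracle", {
  set.seed(41)
  for (rep in 1:20) {
    m <- sample(2:4, 1)
    A <- matrix(stats::rnorm(m * m), m, m)
    q <- simplex_quadratic(A + t(A), stats::rnorm(m))
    x <- minimize_on_simplex(q)
    expect_true(all(x >= -1e-14))
    expect_equal(sum(x), 1, tolerance = 1e-12)
    fx <- eval_simplex_quadratic(q, x)
    ## never worse than any candidate start point
    expect_lte(fx, eval_simplex_quadratic(q, rep(1 / m, m)) + 1e-12)
    for (i in seq_len(m)) {
      expect_lte(fx, eval_simplex_quadratic(q, as.numeric(seq_len(m) == i)) +
                   1e-12)
    }
    grid <- simplex_grid_minimum(q, steps = 100)
    expect_lte(fx, grid$value + 1e-6)
  }
})

test_that("ediis_objective is the exact energy of mixed densities on quadratic models", {
  expect_equal(eval_simplex_quadratic(
    ediis_objective(-2.5, list(list(diag(2))), list(list(diag(c(1, 0))))),
    1), -2.5)
  ## two identical entries: X = 0, objective is linear
  F1 <- list(scfaccel:::random_hermitian(3, "real", seed = 2))
  P1 <- list(diag(c(2, 0, 0)))
  q <- ediis_objective(c(-1, -1), list(F1, F1), list(P1, P1))
  expect_equal(q$A, matrix(0, 2, 2))
  expect_equal(eval_simplex_quadratic(q, c(0.3, 0.7)), -1)
  ## quadratic-energy identity on a synthetic model
  set.seed(43)
  for (field in c("real", "complex")) {
    p <- make_quadratic_problem(4, 1, strength = 1.5, field = field,
                                seed = 101)
    h <- random_model_history(p, 5)
    q <- ediis_objective(h$energies, h$F_list, h$P_list)
    for (k in 1:10) {
      c_ <- random_simplex_point(5)
      Pmix <- lapply(1:1, function(b) {
        Reduce(`+`, mapply(function(w, P) w * P[[b]], c_, h$P_list,
                           SIMPLIFY = FALSE))
      })
      expect_equal(eval_simplex_quadratic(q, c_),
                   Re(model_energy(p, Pmix)), tolerance = 1e-10)
    }
  }
})

test_that("adiis_objective reproduces the reference energy and shares the EDIIS argmin", {
  p <- make_quadratic_problem(4, 1, strength = 1.2, seed = 103)
  set.seed(47)
  h <- random_model_history(p, 4)
  qa <- adiis_objective(h$energies, h$F_list, h$P_list, ref_index = 2)
  ## indicator of the reference recovers E(P_n)
  expect_equal(eval_simplex_quadratic(qa, c(0, 1, 0, 0)), h$energies[2],
               tolerance = 1e-10)
  ## single-entry history: constant at the reference energy
  q1 <- adiis_objective(h$energies[1], h$F_list[1], h$P_list[1], 1)
  expect_equal(eval_simplex_quadratic(q1, 1), h$energies[1])
  ## HF-form equivalence: both objectives locate the same mixed density
  qe <- ediis_objective(h$energies, h$F_list, h$P_list)
  ce <- minimize_on_simplex(qe)
  ca <- minimize_on_simplex(qa)
  expect_equal(eval_simplex_quadratic(qe, ce), eval_simplex_quadratic(qe, ca),
               tolerance = 1e-8)
})

test_that("mesa_select picks the least density change and breaks ties to ADIIS", {
  p <- make_quadratic_problem(3, 1, strength = 1, seed = 107)
  set.seed(53)
  h <- random_model_history(p, 3)
  ## identical candidates: identical result
  sel <- mesa_select(c(1, 0, 0), c(1, 0, 0), h$P_list, h$P_list[[1]])
  expect_equal(sel$weights, c(1, 0, 0))
  expect_equal(sel$label, "adiis")           # tie goes to ADIIS
  ## an indicator of the current entry has zero change and must win
  sel2 <- mesa_select(random_simplex_point(3), c(0, 0, 1),
                      h$P_list, h$P_list[[3]])
  expect_equal(sel2$label, "adiis")
  expect_equal(sel2$weights, c(0, 0, 1))
  ## random candidates match the direct norm comparison
  for (k in 1:10) {
    ce <- random_simplex_point(3)
    ca <- random_simplex_point(3)
    Pcur <- h$P_list[[1]]
    dist <- function(w) {
      Pm <- lapply(seq_along(Pcur), function(b) {
        Reduce(`+`, mapply(function(wi, P) wi * P[[b]], w, h$P_list,
                           SIMPLIFY = FALSE))
      })
      sqrt(sum(vapply(seq_along(Pm), function(b) {
        sum(abs(Pcur[[b]] - Pm[[b]])^2)
      }, numeric(1))))
    }
    sel3 <- mesa_select(ce, ca, h$P_list, Pcur)
    want <- if (dist(ca) <= dist(ce)) "adiis" else "ediis"
    expect_equal(sel3$label, want)
  }
})
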