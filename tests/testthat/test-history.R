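test_that("push_entry implements the lowest-energy-first retention policy", {
  s <- scf_history(10)
  s <- push_entry(s, stub_entry(-1, 1))
  expect_length(s, 1)
  expect_equal(s$entries[[1]]$E_total, -1)

  ## a new minimum takes the head; the old minimum is demoted in order
  s <- scf_history(10)
  s <- push_entry(s, stub_entry(-2, 1))
  s <- push_entry(s, stub_entry(-1, 2))
  s <- push_entry(s, stub_entry(-3, 3))
  expect_equal(vapply(s$entries, `[[`, numeric(1), "E_total"), c(-3, -1, -2))
  expect_equal(vapply(s$entries, `[[`, integer(1), "iteration_index"),
               c(3L, 2L, 1L))

  ## overflow evicts the oldest nonminimal entry, never the minimum
  s <- scf_history(3)
  s <- push_entry(s, stub_entry(-5, 1))   # minimum
  s <- push_entry(s, stub_entry(-1, 4))
  s <- push_entry(s, stub_entry(-2, 5))
  s <- push_entry(s, stub_entry(-1.5, 6))
  expect_length(s, 3)
  expect_equal(s$entries[[1]]$E_total, -5)
  expect_equal(vapply(s$entries, `[[`, integer(1), "iteration_index"),
               c(1L, 6L, 5L))               # it 4 (oldest nonminimal) evicted

  expect_error(push_entry(s, stub_entry(NaN, 7)), "non-finite")
})

test_that("history invariants survive random push sequences", {
  set.seed(11)
  for (rep in 1:20) {
    cap <- sample(2:6, 1)
    s <- scf_history(cap)
    energies <- stats::rnorm(30)
    for (i in seq_along(energies)) {
      s <- push_entry(s, stub_entry(energies[i], i))
      E <- vapply(s$entries, `[[`, numeric(1), "E_total")
      it <- vapply(s$entries, `[[`, integer(1), "iteration_index")
      expect_lte(length(s), cap)
      expect_equal(E[1], min(energies[1:i]))   # minimum pinned at the head
      if (length(it) > 2) expect_true(all(diff(it[-1]) < 0))
    }
  }
})

test_that("cleanup_history drops faraway densities and keeps the head", {
  mk <- function(E, it, p) stub_entry(E, it, p)
  s <- scf_history(10)
  s <- push_entry(s, mk(-3, 1, 0))        # head, P0 = 0
  s <- push_entry(s, mk(-1, 2, 1e-6))
  s <- push_entry(s, mk(-2, 3, 1.0))
  out <- cleanup_history(s, delta_history = 1e-4)
  d <- vapply(out$entries, function(e) abs(e$P[[1]][1, 1]), numeric(1))
  expect_equal(d, c(0, 1e-6))             # 1e-4 * 1.0 > 1e-6: dropped

  ## identical densities: everything retained
  s2 <- scf_history(10)
  for (i in 1:4) s2 <- push_entry(s2, mk(-i, i, 0.5))
  expect_length(cleanup_history(s2), 4)

  ## two entries at distances {0, d}: both retained for any d > 0
  s3 <- scf_history(10)
  s3 <- push_entry(s3, mk(-2, 1, 0))
  s3 <- push_entry(s3, mk(-1, 2, 7.3))
  expect_length(cleanup_history(s3), 2)

  ## single entry unchanged; idempotence
  expect_length(cleanup_history(push_entry(scf_history(5), mk(0, 1, 0))), 1)
  expect_identical(cleanup_history(out), out)
})

test_that("cleanup never evicts the minimum under fuzzing and is idempotent", {
  set.seed(23)
  for (rep in 1:15) {
    s <- scf_history(8)
    for (i in 1:12) {
      s <- push_entry(s, stub_entry(stats::rnorm(1), i, stats::rexp(1)))
    }
    Emin <- s$entries[[1]]$E_total
    out <- cleanup_history(s)
    expect_equal(out$entries[[1]]$E_total, Emin)
    expect_identical(cleanup_history(out)$entries, out$entries)
  }
})

test_that("stagnation_check counts trailing failures against the running best", {
  ## N = 10: the last 5 energies all sit above the running minimum
  expect_true(stagnation_check(c(-2, -1, -1, -1, -1, -1), 10))
  ## 4 failures then an improvement
  expect_false(stagnation_check(c(-2, -1, -1, -1, -1, -3), 10))
  ## not enough evidence yet
  expect_false(stagnation_check(c(-1, -0.5, -0.4), 10))
  expect_false(stagnation_check(numeric(0), 10))
  ## odd capacity rounds up: N = 5 needs 3 trailing failures
  expect_true(stagnation_check(c(-2, -1, -1, -1), 5))
  expect_false(stagnation_check(c(-2, -1, -1), 5))
})

test_that("history stacks round-trip through the JSON container", {
  p <- make_quadratic_problem(3, 1, strength = 0.8, field = "complex",
                              seed = 5)
  res <- solve_scf(p, config = scf_config(max_iterations = 6))
  path <- tempfile(fileext = ".json")
  history_save(res$history, path)
  back <- history_load(path)
  expect_equal(back$capacity, res$history$capacity)
  expect_length(back, length(res$history))
  for (i in seq_along(back$entries)) {
    expect_equal(back$entries[[i]]$E_total, res$history$entries[[i]]$E_total)
    expect_equal(back$entries[[i]]$P, res$history$entries[[i]]$P,
                 tolerance = 1e-12)
    expect_equal(back$entries[[i]]$F, res$history$entries[[i]]$F,
                 tolerance = 1e-12)
  }
  unlink(path)
})
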