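## The SCF driver.  One loop structure serves every particle content: each
## Fock evaluation yields an iteration entry (states, F, P, [F,P], E) that is
## pushed onto the lowest-energy-first history; the next orbitals come from
## diagonalizing an extrapolated Fock matrix whose weights blend DIIS with
## the MESA-selected EDIIS/ADIIS interpolation according to the size of the
## DIIS error, except when the orbital gradient is huge or the accelerated
## iterations have stagnated, in which case the optimal damping algorithm
## takes over.

#' SCF driver configuration
#'
#' All tunables of the solver with their library defaults.
#'
#' @param history_capacity history length `N` (default 10; 20 is a common
#'   choice for hard coupled problems)
#' @param diis_damping Hamilton-Pulay diagonal damping `d` (default 0.02)
#' @param delta_diis DIIS restart-screening parameter (default `1e-4`)
#' @param delta_history history-cleanup parameter (default `1e-4`)
#' @param eps1 DIIS error below which pure DIIS weights are used
#'   (default `1e-4`)
#' @param eps2 DIIS error above which pure EDIIS/ADIIS weights are used
#'   (default `1e-1`)
#' @param oda_threshold max-norm orbital gradient that triggers optimal
#'   damping (default 1; an intensive criterion)
#' @param error_norm_kind `"rms"` (default) or `"max"`; used both for
#'   convergence and for the hybrid switch
#' @param convergence_threshold DIIS error at which the SCF stops
#'   (default `1e-7`)
#' @param max_iterations Fock-evaluation budget (default 200)
#' @param stepwise_macro_threshold energy change below which the stepwise
#'   macroiteration loop hands over to the simultaneous solver
#'   (default `1e-7`)
#' @param max_macro macroiteration cap for [solve_stepwise()] (default 50)
#' @param strategy `"full"` (hybrid + optimal damping + stagnation fallback,
#'   default), `"hybrid"` (no optimal damping), `"diis"` (DIIS only) or
#'   `"roothaan"` (bare fixed-point iteration)
#' @param cleanup_every run the density-based history cleanup before every
#'   extrapolation (default `TRUE`)
#' @param oda_max_bisect bisection cap inside one damping step (default 5)
#' @param oda_max_consecutive cap on consecutive optimal-damping evaluations
#'   per activation (default 50)
#' @param adiis_reference `"newest"` (default) or `"best"` history entry as
#'   the ADIIS expansion point
#' @param mesa_reference `"current"` (default) or `"best"` density used as
#'   the change reference in the EDIIS/ADIIS choice
#' @param diis_normalize `"smallest"` (default) or `"newest"` diagonal
#'   normalization of the DIIS overlap matrix
#' @param validate run Hermiticity checks on every evaluator result
#'   (default `TRUE`)
#' @param seed optional integer stored for provenance
#' @return an object of class `scf_config`
#' @export
scf_config <- function(history_capacity = 10L,
                       diis_damping = 0.02,
                       delta_diis = 1e-4,
                       delta_history = 1e-4,
                       eps1 = 1e-4,
                       eps2 = 1e-1,
                       oda_threshold = 1.0,
                       error_norm_kind = c("rms", "max"),
                       convergence_threshold = 1e-7,
                       max_iterations = 200L,
                       stepwise_macro_threshold = 1e-7,
                       max_macro = 50L,
                       strategy = c("full", "hybrid", "diis", "roothaan"),
                       cleanup_every = TRUE,
                       oda_max_bisect = 5L,
                       oda_max_consecutive = 50L,
                       adiis_reference = c("newest", "best"),
                       mesa_reference = c("current", "best"),
                       diis_normalize = c("smallest", "newest"),
                       validate = TRUE,
                       seed = NULL) {
  stopifnot(eps1 < eps2, eps1 > 0, convergence_threshold > 0,
            delta_diis >= 0, delta_history >= 0, oda_threshold > 0,
            history_capacity >= 1, max_iterations >= 1)
  structure(list(
    history_capacity = as.integer(history_capacity),
    diis_damping = diis_damping, delta_diis = delta_diis,
    delta_history = delta_history, eps1 = eps1, eps2 = eps2,
    oda_threshold = oda_threshold,
    error_norm_kind = match.arg(error_norm_kind),
    convergence_threshold = convergence_threshold,
    max_iterations = as.integer(max_iterations),
    stepwise_macro_threshold = stepwise_macro_threshold,
    max_macro = as.integer(max_macro),
    strategy = match.arg(strategy),
    cleanup_every = isTRUE(cleanup_every),
    oda_max_bisect = as.integer(oda_max_bisect),
    oda_max_consecutive = as.integer(oda_max_consecutive),
    adiis_reference = match.arg(adiis_reference),
    mesa_reference = match.arg(mesa_reference),
    diis_normalize = match.arg(diis_normalize),
    validate = isTRUE(validate),
    seed = seed), class = "scf_config")
}

#' Bundle an SCF problem for the driver
#'
#' @param specs list of [block_spec()] objects
#' @param n_particles numeric vector of particle counts indexed by particle
#'   type
#' @param evaluator function `(C_list, f_list) -> list(E_total, F, ...)`
#'   returning the total energy and per-block Hermitian Fock matrices in the
#'   orthonormal basis; must be deterministic in its inputs
#' @return an object of class `scf_problem`
#' @export
scf_problem <- function(specs, n_particles, evaluator) {
  stopifnot(is.list(specs), length(specs) >= 1, is.function(evaluator))
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  stopifnot(length(n_particles) >= max(types))
  structure(list(specs = specs, n_particles = as.numeric(n_particles),
                 evaluator = evaluator), class = "scf_problem")
}

#' Convert a synthetic model problem into a driver-ready SCF problem
#' @param problem a `model_problem`
#' @return an `scf_problem`
#' @export
as_scf_problem <- function(problem) {
  if (inherits(problem, "scf_problem")) return(problem)
  stopifnot(inherits(problem, "model_problem"))
  scf_problem(problem$specs, problem$n_particles, model_evaluator(problem))
}

#' Roothaan update: diagonalize per-block Fock matrices and refill
#'
#' Per block, the new orbitals are the eigenvectors of `F` ordered by
#' ascending eigenvalue; occupations are assigned by Aufbau filling across
#' each particle type's blocks.
#'
#' @param F_list per-block Hermitian matrices
#' @param specs list of [block_spec()]
#' @param n_particles particle counts indexed by type
#' @return list of [block_state()]
#' @export
roothaan_update <- function(F_list, specs, n_particles) {
  eigs <- lapply(F_list, eigen_ascending)
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  states <- vector("list", length(specs))
  for (t in unique(types)) {
    blocks <- which(types == t)
    f <- aufbau_fill(lapply(blocks, function(b) eigs[[b]]$values),
                     vapply(blocks, function(b) specs[[b]]$f_max, numeric(1)),
                     n_particles[t])
    for (i in seq_along(blocks)) {
      b <- blocks[i]
      states[[b]] <- block_state(eigs[[b]]$vectors, eigs[[b]]$values,
                                 f[[i]], validate = FALSE)
    }
  }
  states
}

#' Hybrid DIIS interpolation factor
#'
#' 0 when the DIIS error is at or above `eps2` (pure EDIIS/ADIIS), 1 at or
#' below `eps1` (pure DIIS), linear in between.
#'
#' @param eps DIIS error
#' @param eps1,eps2 switch thresholds (`eps1 < eps2`)
#' @return value in `[0, 1]`
#' @export
hybrid_interpolation_factor <- function(eps, eps1 = 1e-4, eps2 = 1e-1) {
  if (eps >= eps2) return(0)
  if (eps <= eps1) return(1)
  (eps2 - eps) / (eps2 - eps1)
}

#' Blend DIIS and EDIIS/ADIIS weight vectors
#'
#' `f_int(eps) * c_diis + (1 - f_int(eps)) * c_interp`; both inputs sum to
#' one, hence so does the output.
#'
#' @param eps_diis DIIS error steering the interpolation
#' @param c_diis,c_interp weight vectors of equal length summing to one
#' @param eps1,eps2 switch thresholds
#' @return blended weight vector
#' @export
hybrid_weights <- function(eps_diis, c_diis, c_interp,
                           eps1 = 1e-4, eps2 = 1e-1) {
  stopifnot(length(c_diis) == length(c_interp))
  fint <- hybrid_interpolation_factor(eps_diis, eps1, eps2)
  fint * c_diis + (1 - fint) * c_interp
}

#' Extrapolate Fock matrices with given weights
#'
#' @param F_histories list (length m) of per-block Fock-matrix lists
#' @param weights numeric weights summing to one
#' @return per-block list of extrapolated matrices
#' @export
extrapolate_fock <- function(F_histories, weights) {
  stopifnot(length(F_histories) == length(weights),
            abs(sum(weights) - 1) < 1e-8)
  nb <- length(F_histories[[1]])
  lapply(seq_len(nb), function(b) {
    Reduce(`+`, mapply(function(w, F) w * F[[b]], weights, F_histories,
                       SIMPLIFY = FALSE))
  })
}

## Normalize the various accepted guess forms into a list of block states.
resolve_guess <- function(problem, guess) {
  specs <- problem$specs
  if (is.null(guess)) {
    stop("a guess is required: list(F = ...) or list(C = ..., f = ...)")
  }
  if (is.list(guess) && !is.null(guess$F)) {
    return(roothaan_update(guess$F, specs, problem$n_particles))
  }
  if (is.list(guess) && !is.null(guess$C) && !is.null(guess$f)) {
    return(lapply(seq_along(specs), function(b) {
      C <- guess$C[[b]]
      eps <- seq_len(ncol(C))     # placeholder ordering indices
      block_state(C, eps, guess$f[[b]], validate = FALSE)
    }))
  }
  if (is.list(guess) && all(vapply(guess, inherits, logical(1), "block_state"))) {
    return(guess)
  }
  stop("unrecognized guess format")
}

#' Solve an SCF problem with the simultaneous driver
#'
#' Iterates Fock evaluations until the configured error norm of the
#' commutator `[F, P]` drops below the convergence threshold.  Strategy per
#' iteration (for `strategy = "full"`): if the max-norm orbital gradient is
#' at or above `oda_threshold`, or a stagnation burst is active, take an
#' optimal-damping step from the lowest-energy entry; otherwise clean up the
#' history, compute DIIS weights (screened, damped), compute the EDIIS and
#' ADIIS simplex minimizers, pick one by least density change (MESA), blend
#' with the DIIS weights according to the hybrid interpolation factor,
#' extrapolate the Fock matrices and Roothaan-update.  When
#' `ceiling(N/2)` consecutive accelerated iterations fail to lower the best
#' energy, the next `ceiling(N/2)` Fock evaluations are handed to optimal
#' damping (tit-for-tat fallback).
#'
#' @param problem an [scf_problem()] or `model_problem`
#' @param guess `list(F = per-block Fock guess)` or
#'   `list(C = ..., f = ...)` or a list of [block_state()]; for a
#'   `model_problem` the default is the core-Hamiltonian guess
#' @param config an [scf_config()]
#' @return list with `final` (lowest-energy [iteration_entry()]), `last`
#'   (last iterate), `converged` flag, `n_iterations` (Fock evaluations),
#'   `trace` (data frame: iteration, E_total, E_best, rms_error, max_error,
#'   strategy, f_int, n_history, weights as JSON) and `history`
#' @export
solve_scf <- function(problem, guess = NULL, config = scf_config()) {
  if (inherits(problem, "model_problem")) {
    if (is.null(guess)) guess <- list(F = problem$H)
    problem <- as_scf_problem(problem)
  }
  stopifnot(inherits(problem, "scf_problem"), inherits(config, "scf_config"))
  specs <- problem$specs
  eval_fock <- problem$evaluator

  hist <- scf_history(config$history_capacity)
  trace <- list()
  n_eval <- 0L
  converged <- FALSE

  step_entry <- function(states, label, weights = NULL, f_int = NA_real_) {
    C <- lapply(states, `[[`, "C")
    f <- lapply(states, `[[`, "f")
    out <- eval_fock(C, f)
    if (!is.finite(out$E_total)) {
      stop(sprintf("evaluator returned non-finite energy at iteration %d",
                   n_eval + 1L))
    }
    P <- lapply(states, build_density)
    err <- mapply(commutator_error, out$F, P, SIMPLIFY = FALSE)
    n_eval <<- n_eval + 1L
    entry <- iteration_entry(states, out$F, P, out$E_total, err, n_eval,
                             validate = config$validate)
    hist <<- push_entry(hist, entry)
    rms <- error_norm(err, "rms")
    mx <- error_norm(err, "max")
    trace[[length(trace) + 1L]] <<- data.frame(
      iteration = n_eval, E_total = out$E_total,
      E_best = hist$entries[[1]]$E_total,
      rms_error = rms, max_error = mx, strategy = label, f_int = f_int,
      n_history = length(hist$entries),
      weights = if (is.null(weights)) "" else
        as.character(jsonlite::toJSON(round(weights, 12))),
      stringsAsFactors = FALSE)
    conv_err <- if (config$error_norm_kind == "rms") rms else mx
    if (conv_err < config$convergence_threshold) converged <<- TRUE
    list(entry = entry, rms = rms, max = mx)
  }

  res <- step_entry(resolve_guess(problem, guess), "guess")
  oda_budget <- 0L
  accel_E <- numeric(0)

  while (!converged && n_eval < config$max_iterations) {
    if (config$cleanup_every) {
      hist <- cleanup_history(hist, config$delta_history)
    }
    use_oda <- config$strategy == "full" &&
      (res$max >= config$oda_threshold || oda_budget > 0L)
    if (use_oda) {
      before <- n_eval
      best <- hist$entries[[1]]
      cand <- step_entry(roothaan_update(best$F, specs, problem$n_particles),
                         "oda")
      if (!converged && n_eval < config$max_iterations) {
        final <- oda_relax(best, cand$entry, specs,
                           function(states, label) {
                             step_entry(states, label)$entry
                           },
                           max_bisect = config$oda_max_bisect)
        res <- list(entry = final,
                    rms = error_norm(final$err, "rms"),
                    max = error_norm(final$err, "max"))
      } else {
        res <- cand
      }
      used <- n_eval - before
      if (oda_budget > 0L) oda_budget <- max(0L, oda_budget - used)
      accel_E <- numeric(0)
      next
    }

    if (config$strategy == "roothaan") {
      res <- step_entry(roothaan_update(res$entry$F, specs,
                                        problem$n_particles),
                        "roothaan")
      next
    }

    entries <- hist$entries
    m <- length(entries)
    newest <- which.max(vapply(entries, `[[`, integer(1), "iteration_index"))
    errs <- lapply(entries, `[[`, "err")
    c_diis <- diis_weights(errs, d = config$diis_damping,
                           delta_diis = config$delta_diis, newest = newest,
                           normalize = config$diis_normalize)
    eps <- if (config$error_norm_kind == "rms") res$rms else res$max

    if (config$strategy == "diis" || eps <= config$eps1) {
      wts <- c_diis
      label <- "diis"
      f_int <- 1
    } else {
      energies <- vapply(entries, `[[`, numeric(1), "E_total")
      F_list <- lapply(entries, `[[`, "F")
      P_list <- lapply(entries, `[[`, "P")
      ref <- if (config$adiis_reference == "newest") newest else 1L
      ce <- minimize_on_simplex(ediis_objective(energies, F_list, P_list))
      ca <- minimize_on_simplex(adiis_objective(energies, F_list, P_list,
                                                ref_index = ref))
      P_ref <- if (config$mesa_reference == "current") res$entry$P
               else entries[[1]]$P
      sel <- mesa_select(ce, ca, P_list, P_ref)
      f_int <- hybrid_interpolation_factor(eps, config$eps1, config$eps2)
      wts <- hybrid_weights(eps, c_diis, sel$weights,
                            config$eps1, config$eps2)
      label <- if (f_int <= 0) sel$label else "hybrid"
    }
    Fbar <- extrapolate_fock(lapply(entries, `[[`, "F"), wts)
    res <- step_entry(roothaan_update(Fbar, specs, problem$n_particles),
                      label, weights = wts, f_int = f_int)
    accel_E <- c(accel_E, res$entry$E_total)
    if (config$strategy == "full" &&
        stagnation_check(accel_E, config$history_capacity)) {
      oda_budget <- as.integer(ceiling(config$history_capacity / 2))
      accel_E <- numeric(0)
    }
  }

  list(final = hist$entries[[1]], last = res$entry, converged = converged,
       n_iterations = n_eval, trace = do.call(rbind, trace), history = hist)
}

## Sub-problem with the blocks of one particle-type group active and the
## remaining blocks frozen at the supplied states.  The frozen types'
## contribution to the active Fock matrices (the coupling field) is thereby
## held fixed within the sub-solve and refreshed at macroiteration
## boundaries; the energy returned is always the full energy.
freeze_problem <- function(problem, states, blocks) {
  force(states); force(blocks)
  sub_eval <- function(C_sub, f_sub) {
    C <- lapply(states, `[[`, "C")
    f <- lapply(states, `[[`, "f")
    C[blocks] <- C_sub
    f[blocks] <- f_sub
    out <- problem$evaluator(C, f)
    out$F <- out$F[blocks]
    out
  }
  scf_problem(problem$specs[blocks], problem$n_particles, sub_eval)
}

#' Solve a coupled multi-species problem stepwise, then simultaneously
#'
#' Each macroiteration solves the sub-problem of every particle-type group
#' in turn, with the remaining groups frozen (their coupling field fixed, as
#' in stepwise nuclear-electronic SCF where the inter-species Coulomb matrix
#' is refreshed only at macroiteration boundaries).  When the energy changes
#' by less than `stepwise_macro_threshold` over a macroiteration, the solver
#' switches to the simultaneous driver for the final joint convergence.
#'
#' @param problem an [scf_problem()] or `model_problem`
#' @param partition list of integer vectors grouping particle types
#'   (default: one group per type, in type order)
#' @param guess as in [solve_scf()]
#' @param config an [scf_config()]
#' @return as [solve_scf()], plus `n_macro`, `n_macro_effective` (macros in
#'   which some sub-solve actually moved), `macro_energies` and
#'   `sub_iterations` (Fock evaluations spent in sub-solves)
#' @export
solve_stepwise <- function(problem, partition = NULL, guess = NULL,
                           config = scf_config()) {
  if (inherits(problem, "model_problem")) {
    if (is.null(guess)) guess <- list(F = problem$H)
    problem <- as_scf_problem(problem)
  }
  specs <- problem$specs
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  if (is.null(partition)) {
    partition <- lapply(sort(unique(types)), identity)
  }
  states <- resolve_guess(problem, guess)
  ## initial consistent orbital energies for C/f-style guesses
  macro_E <- numeric(0)
  sub_iters <- 0L
  n_macro <- 0L
  n_macro_eff <- 0L
  repeat {
    n_macro <- n_macro + 1L
    effective <- FALSE
    E_now <- NA_real_
    for (grp in partition) {
      blocks <- which(types %in% grp)
      sub <- freeze_problem(problem, states, blocks)
      res <- solve_scf(sub, guess = states[blocks], config = config)
      sub_iters <- sub_iters + res$n_iterations
      if (res$n_iterations > 1L) effective <- TRUE
      states[blocks] <- res$final$states
      E_now <- res$final$E_total
    }
    macro_E <- c(macro_E, E_now)
    if (effective) n_macro_eff <- n_macro_eff + 1L
    done <- (length(macro_E) >= 2L &&
               abs(diff(utils::tail(macro_E, 2))) <
                 config$stepwise_macro_threshold) ||
      !effective || n_macro >= config$max_macro
    if (done) break
  }
  joint <- solve_scf(problem, guess = states, config = config)
  joint$n_macro <- n_macro
  joint$n_macro_effective <- n_macro_eff
  joint$macro_energies <- macro_E
  joint$sub_iterations <- sub_iters
  joint
}
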