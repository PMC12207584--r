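## Domain types.  A calculation is described by a list of symmetry blocks,
## each belonging to one particle type; the optimizer never needs to know
## what the particles are, only the block dimensions, the per-orbital maximal
## occupations f_max, and the particle count of each type.

#' Describe one symmetry block of a particle type
#'
#' A symmetry block is the elementary unit of the solver: an independent
#' diagonal block of the Fock matrix, labelled by particle type (e.g.
#' spin-up electrons, quantum protons) and irreducible representation.
#' All matrices handed to the solver are per-block and expressed in an
#' orthonormal orbital basis.
#'
#' @param particle_type integer index of the particle type this block belongs
#'   to (types are numbered `1, 2, ...`)
#' @param dim positive integer, number of orbitals in the block
#' @param f_max positive real, maximal occupation of one orbital in this
#'   block (2 for spin-restricted electrons, 1 for spin-orbitals, ...)
#' @param block_label optional text label
#' @return an object of class `block_spec`
#' @export
#' @examples
#' block_spec(1, dim = 4, f_max = 2, block_label = "Ag")
block_spec <- function(particle_type, dim, f_max, block_label = "") {
  stopifnot(length(particle_type) == 1, particle_type >= 1,
            length(dim) == 1, dim >= 1, dim == as.integer(dim),
            length(f_max) == 1, f_max > 0)
  structure(
    list(particle_type = as.integer(particle_type),
         block_label = as.character(block_label),
         dim = as.integer(dim), f_max = as.numeric(f_max)),
    class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("<block_spec> type %d%s, dim %d, f_max %g\n",
              x$particle_type,
              if (nzchar(x$block_label)) paste0(" (", x$block_label, ")") else "",
              x$dim, x$f_max))
  invisible(x)
}

#' Orbital state of one symmetry block
#'
#' @param C `dim x dim` unitary matrix of orbital coefficients in the
#'   orthonormal basis (real or complex)
#' @param E_orb length-`dim` real vector of orbital energies, ascending
#' @param f length-`dim` real vector of orbital occupations, each in
#'   `[0, f_max]`
#' @param validate check unitarity and ordering (default `TRUE`)
#' @return an object of class `block_state`
#' @export
block_state <- function(C, E_orb, f, validate = TRUE) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C),
            length(E_orb) == nrow(C), length(f) == nrow(C))
  E_orb <- as.numeric(E_orb)
  f <- as.numeric(f)
  if (validate) {
    check_unitary(C)
    if (any(diff(E_orb) < -1e-9)) {
      warning("orbital energies are not ascending")
    }
    if (any(f < -1e-10)) stop("negative occupation numbers")
  }
  structure(list(C = C, E_orb = E_orb, f = f), class = "block_state")
}

#' One SCF iterate: states, Fock, density, error and energy
#'
#' Bundles everything the convergence accelerators consume for a single
#' Fock evaluation: per-block orbital states, Fock matrices `F`, density
#' matrices `P` (built as `P = C diag(f) C^H`), the commutator errors
#' `e = [F, P]`, and the total energy.
#'
#' @param states list of [block_state()] objects, one per block
#' @param F list of per-block Hermitian Fock matrices (orthonormal basis)
#' @param P list of per-block Hermitian density matrices
#' @param E_total finite real total energy
#' @param err list of per-block commutator error matrices
#' @param iteration_index integer iteration counter
#' @param validate run Hermiticity/finiteness checks (default `TRUE`)
#' @return an object of class `iteration_entry`
#' @export
iteration_entry <- function(states, F, P, E_total, err, iteration_index,
                            validate = TRUE) {
  stopifnot(length(states) == length(F), length(F) == length(P),
            length(P) == length(err))
  if (!is.finite(E_total)) {
    stop(sprintf("non-finite total energy (%s) in iteration entry", E_total))
  }
  if (validate) {
    for (b in seq_along(F)) {
      check_hermitian(F[[b]], sprintf("Fock matrix (block %d)", b))
      check_hermitian(P[[b]], sprintf("density matrix (block %d)", b))
    }
  }
  structure(
    list(states = states, F = F, P = P, E_total = as.numeric(E_total),
         err = err, iteration_index = as.integer(iteration_index)),
    class = "iteration_entry")
}

#' @export
print.iteration_entry <- function(x, ...) {
  cat(sprintf("<iteration_entry> it %d, E = %.10g, %d block(s)\n",
              x$iteration_index, x$E_total, length(x$F)))
  invisible(x)
}

## Sum of density traces per particle type; used to check particle-number
## conservation against the per-type particle counts.
entry_type_traces <- function(entry, specs) {
  types <- vapply(specs, function(s) s$particle_type, integer(1))
  out <- numeric(max(types))
  for (b in seq_along(specs)) {
    out[types[b]] <- out[types[b]] + Re(sum(diag(entry$P[[b]])))
  }
  out
}
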