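## Aufbau occupation assignment and density-matrix construction.  A particle
## type may own several symmetry blocks; the Aufbau rule fills orbitals of
## all its blocks jointly in order of increasing orbital energy, up to each
## block's maximal per-orbital occupation f_max, leaving at most one
## partially filled orbital.

#' Aufbau filling across the symmetry blocks of one particle type
#'
#' Distributes `n_particles` over the orbitals of all blocks in globally
#' increasing energy order.  Each orbital takes up to its block's `f_max`;
#' the last particles may leave a single fractional occupation.  Orbital
#' energies degenerate to within `1e-12` are ordered deterministically by
#' (block index, orbital index), so permuting block order cannot change the
#' resulting total density of the type.
#'
#' @param orbital_energies list of ascending numeric vectors, one per block
#' @param f_max numeric vector of per-block maximal orbital occupations
#' @param n_particles nonnegative real particle count of this type
#' @param skip_lowest optional integer vector: number of lowest-energy
#'   solutions to skip per block (four-component Dirac-sea style), default 0
#' @return list of per-block occupation vectors; attribute `"n"` carries the
#'   particle count
#' @export
#' @examples
#' aufbau_fill(list(c(-2, -0.5), c(-1, 0.3)), f_max = c(2, 2), n_particles = 3)
aufbau_fill <- function(orbital_energies, f_max, n_particles,
                        skip_lowest = NULL) {
  nb <- length(orbital_energies)
  stopifnot(length(f_max) == nb, n_particles >= 0)
  if (is.null(skip_lowest)) skip_lowest <- rep(0L, nb)
  stopifnot(length(skip_lowest) == nb)
  dims <- lengths(orbital_energies)
  capacity <- sum((dims - skip_lowest) * f_max)
  if (n_particles > capacity + 1e-10) {
    stop(sprintf("cannot place %g particles: capacity is %g",
                 n_particles, capacity))
  }
  blk <- rep(seq_len(nb), dims)
  idx <- unlist(lapply(dims, seq_len), use.names = FALSE)
  e <- unlist(orbital_energies, use.names = FALSE)
  eligible <- idx > skip_lowest[blk]
  ord <- order(e, blk, idx)            # energy first; block/orbital for ties
  ord <- ord[eligible[ord]]
  ## re-sort runs of near-degenerate energies by (block, orbital) so that the
  ## fill order is independent of tiny (< 1e-12) energy noise
  if (length(ord) > 1L) {
    gaps <- diff(e[ord])
    grp <- cumsum(c(0, as.numeric(gaps > 1e-12)))
    ord <- ord[order(grp, blk[ord], idx[ord])]
  }
  f <- lapply(dims, function(d) numeric(d))
  remaining <- n_particles
  for (k in ord) {
    if (remaining <= 0) break
    take <- min(f_max[blk[k]], remaining)
    f[[blk[k]]][idx[k]] <- take
    remaining <- remaining - take
  }
  if (remaining > 1e-10) {
    stop("internal error: particles left over after Aufbau filling")
  }
  structure(f, n = n_particles)
}

#' Build the density matrix of a block state
#'
#' `P = sum_i f_i c_i c_i^H = C diag(f) C^H`, Hermitian with
#' `Tr P = sum_i f_i` and eigenvalues in `[0, f_max]`.
#'
#' @param state a [block_state()] (or any list with elements `C` and `f`)
#' @return Hermitian density matrix
#' @export
build_density <- function(state) {
  C <- state$C
  f <- state$f
  P <- C %*% (f * ct(C))
  hermitize(P)
}
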