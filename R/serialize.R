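## Restart snapshots.  The history stack can be written to a plain-text JSON
## container — one object per entry with datasets C/F/P/f/E_orb/E and the
## iteration index; complex matrices are stored as re/im component pairs.
## The layout is self-describing and round-trips exactly at full double
## precision (digits = NA).

mat_to_json <- function(M) {
  list(nrow = nrow(M), ncol = ncol(M),
       re = as.numeric(Re(M)), im = as.numeric(Im(M)))
}

mat_from_json <- function(m) {
  re <- as.numeric(unlist(m$re))
  im <- as.numeric(unlist(m$im))
  M <- matrix(re, as.integer(m$nrow), as.integer(m$ncol))
  if (any(im != 0)) M <- M + 1i * matrix(im, as.integer(m$nrow),
                                         as.integer(m$ncol))
  M
}

#' Save an SCF history stack to a JSON container
#'
#' @param stack an [scf_history()]
#' @param path file path to write
#' @return `path`, invisibly
#' @export
history_save <- function(stack, path) {
  stopifnot(inherits(stack, "scf_history"))
  obj <- list(
    capacity = stack$capacity,
    entries = lapply(stack$entries, function(e) {
      list(iteration_index = e$iteration_index,
           E = e$E_total,
           C = lapply(e$states, function(s) mat_to_json(s$C)),
           E_orb = lapply(e$states, function(s) s$E_orb),
           f = lapply(e$states, function(s) s$f),
           F = lapply(e$F, mat_to_json),
           P = lapply(e$P, mat_to_json))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an SCF history stack from a JSON container
#'
#' @param path file written by [history_save()]
#' @return an [scf_history()]
#' @export
history_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stack <- scf_history(as.integer(obj$capacity))
  stack$entries <- lapply(obj$entries, function(e) {
    C <- lapply(e$C, mat_from_json)
    F <- lapply(e$F, mat_from_json)
    P <- lapply(e$P, mat_from_json)
    states <- lapply(seq_along(C), function(b) {
      block_state(C[[b]], as.numeric(unlist(e$E_orb[[b]])),
                  as.numeric(unlist(e$f[[b]])), validate = FALSE)
    })
    err <- mapply(commutator_error, F, P, SIMPLIFY = FALSE)
    iteration_entry(states, F, P, as.numeric(e$E), err,
                    as.integer(e$iteration_index), validate = FALSE)
  })
  stack
}
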