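## The history stack.  Convergence acceleration extrapolates over previous
## iterates, so the solver keeps a bounded stack of iteration entries.  Two
## policies distinguish it from a plain ring buffer:
##   * the lowest-energy iterate ever pushed is pinned at position 1 and is
##     never evicted, so the solver can never "forget" its best solution;
##   * remaining entries are kept in decreasing iteration order, and when the
##     stack overflows the oldest non-minimal entry (at the tail) is dropped.

#' Create an empty SCF history stack
#'
#' @param capacity maximal number of retained entries (default 10)
#' @return an object of class `scf_history`
#' @export
scf_history <- function(capacity = 10L) {
  stopifnot(capacity >= 1)
  structure(list(entries = list(), capacity = as.integer(capacity)),
            class = "scf_history")
}

#' @export
print.scf_history <- function(x, ...) {
  cat(sprintf("<scf_history> %d/%d entries", length(x$entries), x$capacity))
  if (length(x$entries)) {
    cat(sprintf(", best E = %.10g (it %d)",
                x$entries[[1]]$E_total, x$entries[[1]]$iteration_index))
  }
  cat("\n")
  invisible(x)
}

#' Number of entries in a history stack
#' @param x an `scf_history`
#' @export
length.scf_history <- function(x) length(x$entries)

#' Push an iteration entry onto the history stack
#'
#' If the new entry has the lowest energy seen it becomes the new head;
#' the previous minimum is demoted to an ordinary entry and re-inserted in
#' iteration order.  Otherwise the entry is inserted right after the head
#' (entries after the head are in decreasing iteration order).  On overflow
#' the oldest non-minimal entry is evicted; the minimum always survives.
#'
#' @param stack an [scf_history()]
#' @param entry an [iteration_entry()]
#' @return the updated stack
#' @export
push_entry <- function(stack, entry) {
  stopifnot(inherits(stack, "scf_history"), inherits(entry, "iteration_entry"))
  if (!is.finite(entry$E_total)) {
    stop("rejecting entry with non-finite total energy")
  }
  entries <- stack$entries
  if (length(entries) == 0L) {
    stack$entries <- list(entry)
    return(stack)
  }
  head <- entries[[1]]
  rest <- entries[-1]
  if (entry$E_total < head$E_total) {
    ## new minimum: old head rejoins the ordinary entries in iteration order
    rest <- c(rest, list(head))
    it <- vapply(rest, function(e) e$iteration_index, integer(1))
    rest <- rest[order(it, decreasing = TRUE)]
    head <- entry
  } else {
    rest <- c(list(entry), rest)
    it <- vapply(rest, function(e) e$iteration_index, integer(1))
    rest <- rest[order(it, decreasing = TRUE)]
  }
  ## evict the oldest non-minimal entry (tail of `rest`) while over capacity
  while (length(rest) + 1L > stack$capacity) {
    rest <- rest[-length(rest)]
  }
  stack$entries <- c(list(head), rest)
  stack
}

#' Drop faraway iterates from the history
#'
#' Retains entry `i` only if `delta_history * ||P_i - P_0||_F` does not
#' exceed the smallest distance among the other candidates, where `P_0` is
#' the density of the lowest-energy entry (the head) and the Frobenius norm
#' is accumulated over all blocks and particle types.  The head itself is
#' always retained, and its zero self-distance is excluded from the minimum
#' (otherwise everything else would always be dropped).  When the orbitals
#' undergo large occupation changes this effectively clears the history down
#' to the iterates near the current basin.
#'
#' @param stack an [scf_history()] whose head is the lowest-energy entry
#' @param delta_history retention parameter (default `1e-4`)
#' @return the filtered stack
#' @export
cleanup_history <- function(stack, delta_history = 1e-4) {
  stopifnot(inherits(stack, "scf_history"))
  entries <- stack$entries
  if (length(entries) <= 1L) return(stack)
  P0 <- entries[[1]]$P
  dist <- vapply(entries[-1], function(e) {
    sqrt(sum(vapply(seq_along(P0), function(b) {
      sum(abs(e$P[[b]] - P0[[b]])^2)
    }, numeric(1))))
  }, numeric(1))
  dmin <- min(dist)
  keep <- delta_history * dist <= dmin
  stack$entries <- c(entries[1], entries[-1][keep])
  stack
}

#' Detect stagnation of the accelerated iterations
#'
#' Returns `TRUE` when the last `ceil(N/2)` consecutive accelerated
#' iterations each failed to lower the best energy seen so far — the signal
#' for the tit-for-tat fallback that hands the next `ceil(N/2)` iterations
#' to the optimal damping algorithm.
#'
#' @param recent_energies numeric vector of accelerated-iteration energies in
#'   iteration order
#' @param capacity history capacity `N`
#' @return logical
#' @export
stagnation_check <- function(recent_energies, capacity) {
  need <- ceiling(capacity / 2)
  n <- length(recent_energies)
  if (n == 0L) return(FALSE)
  ## an iteration "fails" if it does not improve on the best energy before it
  best <- cummin(recent_energies)
  fails <- c(FALSE, recent_energies[-1] >= best[-n] - 0)
  trailing <- 0L
  for (i in rev(seq_len(n))) {
    if (fails[i]) trailing <- trailing + 1L else break
  }
  trailing >= need
}
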