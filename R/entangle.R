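# Chains straddling the periodic boundary are rebuilt as continuous
# polylines before any path analysis.
unwrap_chains <- function(x, topology, box) {
  cr <- chain_ranges(topology)
  out <- x
  for (c in seq_len(nrow(cr))) {
    for (i in (cr$from[c] + 1L):max(cr$from[c] + 1L, cr$to[c])) {
      if (i > cr$to[c]) break
      d <- cpp_min_image(out[i - 1L, ], x[i, ], unclass(box))
      out[i, ] <- out[i - 1L, ] + d
    }
  }
  out
}

#' Primitive paths by constrained chain shrinking
#'
#' Keeps every chain's termini fixed and iteratively shortens its contour
#' by vertex-removal and vertex-straightening moves, rejecting any move
#' whose swept triangle crosses another chain (with X/Y periodic images).
#' An isolated chain shrinks to the straight segment between its termini;
#' interlocked chains retain kinks where the partner blocks them.
#'
#' @param state a `dsb_state`, or an N x 3 coordinate matrix with `box`.
#' @param topology the matching [dsb_topology()].
#' @param box a [dsb_box()] when `state` is a bare matrix.
#' @param periodic use X/Y periodic images in the crossing tests.
#' @param tol convergence: relative contour-length decrease per sweep.
#' @param max_sweeps iteration cap; non-convergence is flagged, not an
#'   error.
#' @return list of per-chain primitive-path matrices, with attributes
#'   `sweep_lengths` and `converged`.
#' @export
shrink_chains <- function(state, topology, box = NULL, periodic = TRUE,
                          tol = 1e-6, max_sweeps = 200L) {
  z <- entanglements(state, topology, box = box, periodic = periodic,
                     tol = tol, max_sweeps = max_sweeps)
  out <- z$paths
  attr(out, "sweep_lengths") <- z$sweep_lengths
  attr(out, "converged") <- z$converged
  out
}

#' Pairwise entanglements from primitive paths
#'
#' Shrinks every chain to its primitive path and counts the unordered
#' chain pairs with at least one kink: a surviving path vertex whose
#' removal is blocked by the partner chain.  Kink locations are reported
#' for rendering.
#'
#' @inheritParams shrink_chains
#' @return An object of class `dsb_entanglements`: `n_entanglements`,
#'   `entangled_pairs` (chain index pairs), `kinks` (locations with the
#'   blocking chain), `paths`, `sweep_lengths`, `converged`.
#' @examples
#' h <- generate_fixture("interlocked_hooks")
#' entanglements(h$x, h$topology, box = h$box, periodic = FALSE)
#' @export
entanglements <- function(state, topology, box = NULL, periodic = TRUE,
                          tol = 1e-6, max_sweeps = 200L) {
  if (inherits(state, "dsb_state")) {
    x <- state$x
    box <- state$box
  } else x <- as.matrix(state)
  if (is.null(box)) stop("a box is required")
  xu <- unwrap_chains(x, topology, box)
  z <- cpp_z1(xu, topology$chain_id, box$Lx, box$Ly, isTRUE(periodic),
              tol, as.integer(max_sweeps))
  if (!z$converged)
    warning("primitive-path shrinking did not reach the length tolerance")
  structure(z, class = "dsb_entanglements")
}

#' Count entangled pairs from already-shrunk paths
#'
#' @param paths a [shrink_chains()] result (list of polyline matrices).
#' @param box a [dsb_box()].
#' @param periodic use X/Y periodic images in the blocking tests.
#' @return An object of class `dsb_entanglements`.
#' @export
count_entanglements <- function(paths, box, periodic = TRUE) {
  lens <- vapply(paths, nrow, 1L)
  x <- do.call(rbind, paths)
  chain <- rep(seq_along(paths), lens)
  top <- list(chain_id = as.integer(chain))
  z <- cpp_z1(x, top$chain_id, box$Lx, box$Ly, isTRUE(periodic),
              1e-6, 50L)
  structure(z, class = "dsb_entanglements")
}

#' @export
print.dsb_entanglements <- function(x, ...) {
  cat(sprintf("entanglements: %d pair(s), %d kink(s)%s\n",
              x$n_entanglements, nrow(x$kinks),
              if (!x$converged) " [not converged]" else ""))
  if (x$n_entanglements > 0) print(x$entangled_pairs)
  invisible(x)
}
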