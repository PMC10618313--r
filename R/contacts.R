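#' Per-residue local frames for directional contacts
#'
#' For every chain-interior residue i, a unit normal (whose negative
#' direction approximates the side chain) from the in-plane bisector of the
#' (i-1, i, i+1) bend, and a unit binormal (the backbone hydrogen-bond
#' direction) from the cross product of the two adjacent bond vectors.
#' Chain termini and collinear triples have no frame and are flagged.
#'
#' @param state a `dsb_state` (or an N x 3 position matrix with `box`).
#' @param topology the matching [dsb_topology()].
#' @param box a [dsb_box()] when `state` is a bare matrix.
#' @return list with `normal` (N x 3), `binormal` (N x 3) and `ok`
#'   (logical N; FALSE where the frame is undefined).
#' @export
local_frames <- function(state, topology, box = NULL) {
  if (inherits(state, "dsb_state")) {
    x <- state$x
    box <- state$box
  } else x <- as.matrix(state)
  cpp_local_frames(x, unclass(box), unclass(topology))
}

#' Contact candidates eligible to switch on
#'
#' Pairs within the capture range of their contact distance whose
#' directional cosines pass the kind-specific thresholds and whose
#' residues have spare coordination capacity.  Backbone criteria use the
#' binormal alignment with the pair direction; side-chain criteria require
#' the negative normal to point toward the partner.  `j = i + 2` pairs and
#' bonded neighbours are never eligible; Go-mapped pairs are permanently
#' attractive and never appear here.
#'
#' @param state a `dsb_state`.
#' @param topology the matching [dsb_topology()].
#' @param params a [dsb_params()].
#' @return data frame of candidates: `i`, `j`, `kind`
#'   (bb/bs/sb/ss/disulfide), `r`, `r0`, sorted by distance then (i, j).
#' @export
eligible_contacts <- function(state, topology, params = dsb_params()) {
  d <- cpp_candidates(state$x, unclass(state$box), unclass(topology),
                      unclass(params), state$registry)
  d$kind <- KIND_LABELS[d$kind]
  d
}

#' Advance the dynamic contact registry
#'
#' One registry maintenance pass over `dtau` time units: contacts whose
#' distance exceeds the rupture threshold start switching off, eligible
#' candidates are admitted (greedy by distance, then lexicographic, under
#' the coordination limits; a cysteine holds at most one disulfide), wall
#' adhesion records are created when enabled, and every activation ramps
#' linearly by `dtau / switch_time` (removed on reaching zero).
#'
#' @param state a `dsb_state`.
#' @param topology the matching [dsb_topology()].
#' @param params a [dsb_params()].
#' @param dtau time advance for the activation ramps (default one step).
#' @return the state with an updated registry.
#' @export
update_registry <- function(state, topology, params = dsb_params(),
                            dtau = params$dt) {
  out <- cpp_registry_step(state$x, unclass(state$box), unclass(topology),
                           unclass(params), state$registry, dtau)
  state$registry <- out$registry
  attr(state$registry, "max_disulfides_per_cys") <-
    out$max_disulfides_per_cys
  state
}

#' Effective side-chain coordination limits under the solvation rule
#'
#' The optional solvation adjustment counts the neighbours within
#' `solvation_radius` (0.75 nm) of each residue; residues with more than
#' `solvation_n_t` neighbours have their side-chain coordination limit
#' changed by one (`solvation_delta`).  Disabled (`n_t = 0`, the default
#' model) it returns the unmodified per-type limits.
#'
#' @param state a `dsb_state`.
#' @param topology the matching [dsb_topology()].
#' @param params a [dsb_params()].
#' @return integer vector of per-residue side-chain coordination limits.
#' @export
solvation_adjustment <- function(state, topology, params = dsb_params()) {
  cpp_effective_nc_ss(state$x, unclass(state$box), unclass(topology),
                      unclass(params))
}
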