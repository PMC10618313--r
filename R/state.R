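#' Simulation box: periodic X/Y, solid walls in Z
#'
#' The cell is a parallelepiped with in-plane vectors `a = (Lx, 0, 0)` and
#' `b = (tilt, Ly, 0)` (tilt is the shear offset, 0 for a rectangular box)
#' and solid walls at `zlo` and `zhi`.  X and Y are periodic; Z is not.
#'
#' @param Lx,Ly in-plane cell edge lengths (Angstrom).
#' @param zlo,zhi wall positions along Z (Angstrom).
#' @param tilt shear offset of the b vector (Angstrom).
#' @param adhesion logical; are the adhesive wall wells enabled?
#' @return An object of class `dsb_box`.
#' @export
dsb_box <- function(Lx, Ly, zlo, zhi, tilt = 0, adhesion = FALSE) {
  if (Lx <= 0 || Ly <= 0 || zhi <= zlo) stop("degenerate box")
  structure(list(Lx = Lx, Ly = Ly, tilt = tilt, zlo = zlo, zhi = zhi,
                 adhesion = isTRUE(adhesion)),
            class = "dsb_box")
}

#' @export
print.dsb_box <- function(x, ...) {
  cat(sprintf("box: %.2f x %.2f x %.2f A (tilt %.2f), walls z = [%.2f, %.2f]%s\n",
              x$Lx, x$Ly, x$zhi - x$zlo, x$tilt, x$zlo, x$zhi,
              if (x$adhesion) ", adhesive" else ""))
  invisible(x)
}

#' Box volume in cubic Angstrom
#' @param box a [dsb_box()].
#' @return volume (A^3); the in-plane shear does not change it.
#' @export
box_volume <- function(box) box$Lx * box$Ly * (box$zhi - box$zlo)

#' Residue density of a simulation state
#'
#' The number of amino-acid residues per cubic nanometer of box volume --
#' the implicit-solvent proxy for protein concentration.
#'
#' @param state a `dsb_state`, or a number of residues when `box` is given.
#' @param box a [dsb_box()] (only when `state` is a residue count).
#' @return density in nm^-3.
#' @examples
#' residue_density(1000, dsb_box(100, 100, 0, 100))  # 1 nm^-3
#' @export
residue_density <- function(state, box = NULL) {
  if (inherits(state, "dsb_state")) {
    n <- nrow(state$x)
    box <- state$box
  } else {
    n <- as.numeric(state)
    if (is.null(box)) stop("give a box when passing a residue count")
  }
  v <- box_volume(box)
  if (!is.finite(v) || v <= 0) stop("degenerate box")
  n / (v / 1000)  # A^3 -> nm^3
}

#' Cubic box side for a target residue density
#'
#' Inverse of [residue_density()] for cubic boxes:
#' `side = (n/rho)^(1/3)` in nm.
#'
#' @param n_residues residue count.
#' @param rho target density (nm^-3).
#' @return side length in nm.
#' @examples
#' box_side_for_density(4271, 3.5)  # ~10.7 nm
#' @export
box_side_for_density <- function(n_residues, rho) {
  if (n_residues <= 0 || rho <= 0) stop("need positive residue count and density")
  (n_residues / rho)^(1 / 3)
}

#' Minimum-image displacement between two points
#'
#' Shortest displacement from `r_i` to `r_j` under the X/Y periodicity of
#' the (possibly sheared) cell; Z is never wrapped.
#'
#' @param r_i,r_j positions, length-3 numeric vectors (Angstrom).
#' @param box a [dsb_box()].
#' @return length-3 displacement vector.
#' @export
minimum_image <- function(r_i, r_j, box) {
  stopifnot(length(r_i) == 3, length(r_j) == 3)
  as.numeric(cpp_min_image(as.numeric(r_i), as.numeric(r_j),
                           unclass(box)))
}

empty_registry <- function() {
  data.frame(i = integer(), j = integer(), kind = integer(),
             r0 = numeric(), depth = numeric(), lambda = numeric(),
             dir = integer())
}

KIND_LABELS <- c("bb", "bs", "sb", "ss", "disulfide", "go", "wall")

go_registry <- function(topology) {
  go <- topology$go_contacts
  if (!nrow(go)) return(empty_registry())
  data.frame(i = go$i, j = go$j, kind = 6L, r0 = go$r0, depth = 1,
             lambda = 1, dir = 0L)
}

#' Construct a simulation state
#'
#' Bundles positions, velocities, box, the dynamic contact registry and the
#' integrator's random-number state.  Permanent Go-contact records from the
#' topology are installed in the registry.
#'
#' @param x N x 3 position matrix (Angstrom).
#' @param v N x 3 velocity matrix (A/tau); defaults to zero.
#' @param box a [dsb_box()].
#' @param topology the matching [dsb_topology()].
#' @param seed integer seed for the simulation RNG.
#' @param time elapsed time (tau).
#' @return An object of class `dsb_state`.
#' @export
dsb_state <- function(x, box, topology, v = NULL, seed = 1L, time = 0) {
  x <- as.matrix(x)
  if (ncol(x) != 3 || nrow(x) != topology$n_residues)
    stop("positions must be an N x 3 matrix matching the topology")
  if (!all(is.finite(x))) stop("non-finite positions")
  if (any(x[, 3] < box$zlo) || any(x[, 3] > box$zhi))
    stop("residues outside the walls")
  if (is.null(v)) v <- matrix(0, nrow(x), 3)
  s <- list(x = x, v = as.matrix(v), box = box,
            registry = go_registry(topology),
            rng = cpp_rng_init(as.integer(seed)), time = time,
            topology_hash = topology$n_residues)
  class(s) <- "dsb_state"
  s
}

#' Draw Maxwell-Boltzmann velocities for a state
#' @param state a `dsb_state`.
#' @param params a [dsb_params()] (for `kBT` and mass).
#' @return the state with thermal velocities (deterministic given its RNG).
#' @export
thermalize <- function(state, params) {
  n <- 3L * nrow(state$x)
  g <- cpp_rng_gauss(state$rng, n)
  state$v <- matrix(g[seq_len(n)] * sqrt(params$kBT / params$mass),
                    ncol = 3)
  state$rng <- g[n + (1:2)]
  state
}

#' @export
print.dsb_state <- function(x, ...) {
  cat(sprintf("DSB state: %d residues, t = %.1f tau, rho = %.3f nm^-3\n",
              nrow(x$x), x$time, residue_density(x)))
  print(x$box)
  cat(sprintf("  active contact records: %d\n", nrow(x$registry)))
  invisible(x)
}

#' @export
summary.dsb_state <- function(object, ...) {
  reg <- object$registry
  kinds <- table(factor(KIND_LABELS[reg$kind], levels = KIND_LABELS))
  out <- list(n_residues = nrow(object$x), time = object$time,
              rho = residue_density(object), contacts = kinds)
  class(out) <- "summary.dsb_state"
  out
}

#' @export
print.summary.dsb_state <- function(x, ...) {
  cat(sprintf("%d residues at t = %.1f tau, rho = %.3f nm^-3\n",
              x$n_residues, x$time, x$rho))
  cat("contact records by kind:\n")
  print(x$contacts)
  invisible(x)
}

#' Export the contact registry as a labelled table
#'
#' @param state a `dsb_state`.
#' @param path optional file; when given, the table is written
#'   tab-separated for debugging and the path returned invisibly.
#' @return data frame with columns `i`, `j`, `kind` (label), `r0`, `depth`,
#'   `lambda`, `dir`.
#' @export
contact_table <- function(state, path = NULL) {
  d <- state$registry
  d$kind <- KIND_LABELS[d$kind]
  if (!is.null(path)) {
    write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  d
}
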