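#' Grid-of-balls cavity detection
#'
#' Lays a cubic grid of probe balls (radius 1.9 A, spacing 1 A by default)
#' over the box, marks balls overlapping any residue as occupied, flood
#' fills the empty balls reachable from outside the slab (through the X/Y
#' periodic images and the open Z faces), and clusters the remaining
#' interior empties into cavities.  Cavity volume is the ball count times
#' the grid cell volume.  With more than one grid rotation (about Z), a
#' ball counts as cavity only if it is interior in every rotation.
#'
#' @param state a `dsb_state`, an N x 3 coordinate matrix (with `box`), or
#'   the path of a PDB file (box taken from its CRYST1 record unless given).
#' @param box a [dsb_box()] when `state` is not a `dsb_state`.
#' @param ball_radius probe ball radius (A).
#' @param residue_radius occlusion radius of a residue bead (A); default
#'   3.8 A, the coarse-grained length unit.
#' @param spacing grid spacing (A); must not exceed the ball diameter.
#' @param rotations number of grid rotations (1 = none, as in the
#'   reference protocol).
#' @param connectivity 6 (faces) or 26 (faces+edges+corners) adjacency for
#'   the flood fill.
#' @param return_balls include the cavity ball centres in the report.
#' @return An object of class `dsb_cavities`: `n_cavities`, `volumes`
#'   (nm^3, descending), `V_C_max`, `V_C_total`, grid parameters, and
#'   optionally `balls` (x, y, z, cavity id).
#' @examples
#' sh <- generate_fixture("hollow_shell", inner_radius = 10)
#' spaceball(sh$x, box = sh$box)$n_cavities  # 1
#' @export
spaceball <- function(state, box = NULL, ball_radius = 1.9,
                      residue_radius = 3.8, spacing = 1,
                      rotations = 1L, connectivity = 6,
                      return_balls = FALSE) {
  if (inherits(state, "dsb_state")) {
    x <- state$x
    box <- state$box
  } else if (is.character(state)) {
    fr <- read_frame(state)
    x <- fr$x
    if (is.null(box)) box <- fr$box
  } else x <- as.matrix(state)
  if (is.null(box)) stop("a box is required")
  if (abs(box$tilt) > 1e-9)
    stop("cavity detection requires a rectangular (untilted) cell")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  out <- cpp_spaceball(x, box$Lx, box$Ly, box$zlo, box$zhi, ball_radius,
                       residue_radius, spacing, as.integer(rotations),
                       connectivity == 26, isTRUE(return_balls))
  volumes <- out$volumes / 1000  # A^3 -> nm^3
  rep <- list(n_cavities = out$n_cavities, volumes = volumes,
              V_C_max = if (length(volumes)) max(volumes) else 0,
              V_C_total = sum(volumes),
              n_occupied = out$n_occupied, n_outside = out$n_outside,
              n_cavity_balls = out$n_cavity_balls,
              ball_radius = ball_radius, residue_radius = residue_radius,
              spacing = spacing, rotations = rotations)
  if (!is.null(out$balls)) {
    b <- as.data.frame(out$balls)
    names(b) <- c("x", "y", "z", "cavity")
    rep$balls <- b
  }
  class(rep) <- "dsb_cavities"
  rep
}

#' @export
print.dsb_cavities <- function(x, ...) {
  cat(sprintf(
    "cavities: %d found, V_C_max = %.3f nm^3, total %.3f nm^3\n",
    x$n_cavities, x$V_C_max, x$V_C_total))
  cat(sprintf("  (ball %.2f A, residue %.2f A, spacing %.2f A, %d rotation(s))\n",
              x$ball_radius, x$residue_radius, x$spacing, x$rotations))
  invisible(x)
}

#' Cavity statistics across a density sweep
#'
#' Per-density averages (with standard errors) of the cavity count, the
#' biggest-cavity volume and the total cavity volume, computed near the
#' end of each run.
#'
#' @param sweep a [density_sweep()] result.
#' @return data frame: `rho`, `n_cavities`, `V_C_max`, `V_C_total`, each
#'   with an `_se` companion.
#' @export
cavity_vs_density <- function(sweep) {
  s <- sweep$summary
  s <- s[s$var %in% c("n_cavities", "V_C_max", "V_C_total") &
           !is.na(s$mean), ]
  if (!nrow(s))
    return(data.frame(rho = numeric(), n_cavities = numeric(),
                      V_C_max = numeric(), V_C_total = numeric()))
  wide <- stats::reshape(s, idvar = "rho", timevar = "var",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  names(wide) <- sub("^se\\.(.*)$", "\\1_se", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$rho), ]
}
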