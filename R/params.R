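#' @useDynLib dsbsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd setNames aggregate
#' @importFrom utils read.table write.csv head modifyList
NULL

# One-letter amino-acid alphabet used for all per-type tables.
AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Stand-in side-chain size scale (Angstrom), ordered as AA_CODES.  Used to
# build the default ss pair-distance matrix as the mean of the two
# per-residue values; roughly tracks side-chain volume.
AA_SIGMA <- c(A = 5.0, C = 5.5, D = 5.6, E = 6.0, F = 6.4, G = 4.5, H = 6.2,
              I = 6.2, K = 6.3, L = 6.2, M = 6.2, N = 5.7, P = 5.6, Q = 6.1,
              R = 6.5, S = 5.1, T = 5.5, V = 5.9, W = 6.8, Y = 6.5)[AA_CODES]

#' Model parameters for the DSB coarse-grained force field
#'
#' Builds the parameter set of the one-bead-per-residue dynamic
#' structure-based (DSB) model.  Internal units are Angstrom (length),
#' epsilon (energy), tau (time, roughly 1 ns) and the average residue mass;
#' one tau equals 200 integration steps, so `dt = tau/200`.
#'
#' The printed constants of the model are the defaults: bond spring
#' `k_bond = 50` eps/A^2 with minimum 3.8 A, excluded-volume cutoff 5 A,
#' backbone-backbone contact distance 5 A, backbone-side chain 6.8 A,
#' contact depth eps, disulfide and wall-adhesion depth 4 eps,
#' quasi-adiabatic switching time 10 tau, rupture threshold
#' `3/2 * r0 / 2^(1/6)`, `gamma = 2 m / tau` and `0.3 <= kBT/eps <= 0.38`
#' at room temperature.  Quantities the model needs but that have no
#' published value (side-chain pair-distance matrix, coordination-number
#' tables, directional cosine cutoffs, Debye length, angle/dihedral tables)
#' ship as documented stand-in defaults and are all overridable here.
#'
#' @param kBT thermal energy in eps (room temperature is 0.3--0.38).
#' @param mass residue mass in units of the average amino-acid mass.
#' @param epsilon energy unit (leave at 1 to work in eps).
#' @param debye_length Debye screening length in Angstrom.
#' @param solvation_n_t neighbour-count threshold for the solvation rule;
#'   0 disables the rule (the default model).
#' @param solvation_delta +1 or -1: direction in which the side-chain
#'   coordination limit changes when the neighbour count exceeds the
#'   threshold.
#' @param ... any other parameter listed in the details, overriding its
#'   default (e.g. `cos_bb = 0.7`, `contact_stride = 5`).
#' @return An object of class `dsb_params` (a named list).
#' @examples
#' p <- dsb_params(kBT = 0.35)
#' p$k_bond
#' @export
dsb_params <- function(kBT = 0.35, mass = 1, epsilon = 1,
                       debye_length = 10, solvation_n_t = 0,
                       solvation_delta = 1L, ...) {
  tau <- 1
  r_ss <- outer(AA_SIGMA, AA_SIGMA, function(a, b) (a + b) / 2)
  dimnames(r_ss) <- list(AA_CODES, AA_CODES)
  nc_bb <- rep(2L, 20)
  names(nc_bb) <- AA_CODES
  nc_bb["P"] <- 1L  # proline cannot donate a backbone hydrogen bond
  big <- AA_CODES %in% c("F", "W", "Y", "L", "I", "M", "V")
  nc_ss <- ifelse(big, 3L, 2L)
  names(nc_ss) <- AA_CODES
  charge <- setNames(rep(0, 20), AA_CODES)
  charge[c("D", "E")] <- -1
  charge[c("K", "R")] <- 1
  p <- list(
    epsilon = epsilon, tau = tau, dt = tau / 200, mass = mass,
    gamma = 2 * mass / tau, kBT = kBT,
    k_bond = 50, r_bond = 3.8, r_excl = 5, r_bb = 5, r_bs = 6.8,
    r_ss = r_ss, nc_bb = nc_bb, nc_ss = nc_ss, charge = charge,
    depth_contact = 1, depth_disulfide = 4,
    kappa_perm = 4, debye_length = debye_length,
    coulomb_k = 332.0637 / 1.5,  # e^2/(4 pi eps0) with eps ~ 1.5 kcal/mol
    switch_time = 10, breakage_factor = 1.5, capture_factor = 1.1,
    cos_bb = 0.5, cos_bs = 0.5, cos_ss = 0.5,
    wall_sigma = 5, wall_adhesion_depth = 4, wall_adhesion_r0 = 5,
    wall_printed_sign = FALSE, walls_enabled = TRUE,
    solvation_n_t = as.integer(solvation_n_t),
    solvation_radius = 7.5, solvation_delta = as.integer(solvation_delta),
    contact_stride = 1L, verlet_skin = 2,
    use_angle_potentials = TRUE,
    angle_table = default_angle_table(),
    dihedral_table = default_dihedral_table())
  extra <- list(...)
  if (length(extra)) {
    bad <- setdiff(names(extra), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(extra)] <- extra
  }
  stopifnot(abs(p$dt * 200 - p$tau) < 1e-12,
            abs(p$gamma - 2 * p$mass / p$tau) < 1e-12)
  dists <- c(p$k_bond, p$r_bond, p$r_excl, p$r_bb, p$r_bs, p$r_ss,
             p$wall_sigma, p$debye_length)
  if (any(dists <= 0)) stop("all distances must be positive")
  class(p) <- "dsb_params"
  p
}

# Smooth synthetic stand-in for the random-coil bond-angle potential:
# a soft well centred on the typical C-alpha pseudo-angle.
default_angle_table <- function(n = 61) {
  th <- seq(0, pi, length.out = n)
  list(x = th, y = 2.0 * (th - 1.9)^2)
}

# Smooth synthetic periodic stand-in for the random-coil dihedral potential.
default_dihedral_table <- function(n = 72) {
  ph <- seq(-pi, pi - 2 * pi / n, length.out = n)
  list(x = ph, y = 0.4 * (1 + cos(ph)) + 0.2 * (1 + cos(3 * ph)))
}

#' @export
print.dsb_params <- function(x, ...) {
  cat("DSB model parameters\n")
  cat(sprintf("  kBT = %.3g eps, dt = tau/%d, gamma = %.3g m/tau\n",
              x$kBT, round(x$tau / x$dt), x$gamma / x$mass * x$tau))
  cat(sprintf("  bonds: k = %g eps/A^2, r_b = %g A; excluded volume cut %g A\n",
              x$k_bond, x$r_bond, x$r_excl))
  cat(sprintf("  contacts: bb %g A, bs %g A, ss %.1f-%.1f A, depth %g eps, disulfide %g eps\n",
              x$r_bb, x$r_bs, min(x$r_ss), max(x$r_ss),
              x$depth_contact, x$depth_disulfide))
  cat(sprintf("  switching %g tau, rupture at %g*r0/2^(1/6), capture %g*r0\n",
              x$switch_time, x$breakage_factor, x$capture_factor))
  cat(sprintf("  walls: sigma %g A, adhesion depth %g eps; Debye length %g A\n",
              x$wall_sigma, x$wall_adhesion_depth, x$debye_length))
  if (x$solvation_n_t > 0)
    cat(sprintf("  solvation rule: n_t = %d, delta = %+d\n",
                x$solvation_n_t, x$solvation_delta))
  invisible(x)
}

#' Read a tabulated angle or dihedral potential
#'
#' Two whitespace-separated columns: coordinate (radians) and energy (eps).
#' Angle tables must cover `[0, pi]`; dihedral tables are periodic on
#' `(-pi, pi]`.
#'
#' @param path file path.
#' @return list with components `x` and `y` suitable for
#'   [dsb_params()]'s `angle_table`/`dihedral_table`.
#' @export
read_potential_table <- function(path) {
  d <- read.table(path, header = FALSE)
  if (ncol(d) < 2) stop("potential table needs two columns")
  o <- order(d[[1]])
  list(x = as.numeric(d[[1]][o]), y = as.numeric(d[[2]][o]))
}
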