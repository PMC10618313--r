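#' Harmonic backbone bond energy and force
#'
#' `V(r) = k (r - r_b)^2` with the spring constant in eps/A^2 (no 1/2
#' factor, matching the stated units of k).
#'
#' @param r bond length(s), Angstrom.
#' @param params a [dsb_params()].
#' @return data frame with `energy` (eps) and `force` (eps/A, the radial
#'   component `-dV/dr`).
#' @examples
#' bond_energy(3.8)           # zero at the minimum
#' bond_energy(4.8)$energy    # 50 eps
#' @export
bond_energy <- function(r, params = dsb_params()) {
  if (any(r <= 0)) stop("bond length must be positive")
  dr <- r - params$r_bond
  data.frame(r = r, energy = params$k_bond * dr^2,
             force = -2 * params$k_bond * dr)
}

#' Excluded-volume potential
#'
#' Lennard-Jones repulsion cut and shifted at `r0`:
#' `V(r <= r0) = eps ((r0/r)^12 - 2 (r0/r)^6 + 1)`, exactly zero for
#' `r > r0`, continuous (with continuous derivative) at the cutoff.
#'
#' @param r distance(s), Angstrom; must be positive.
#' @param r0 cutoff (default 5 A).
#' @param epsilon energy scale.
#' @return energy in eps.
#' @examples
#' excluded_volume(5)            # 0 at the cutoff
#' excluded_volume(5 / 2^(1/6))  # 1 eps
#' @export
excluded_volume <- function(r, r0 = 5, epsilon = 1) {
  if (any(r <= 0)) stop("distance must be positive")
  s6 <- (r0 / r)^6
  ifelse(r > r0, 0, epsilon * (s6^2 - 2 * s6 + 1))
}

#' Contact well (full 6-12 Lennard-Jones)
#'
#' The attractive well used for bb/bs/ss/Go/disulfide contacts: depth
#' `-depth` at `r = r0`.
#'
#' @param r distance(s), Angstrom.
#' @param r0 equilibrium distance of the contact type (bb 5 A, bs 6.8 A,
#'   ss from the pair matrix, Go from the map).
#' @param depth well depth in eps (contacts 1, disulfides and wall
#'   adhesion 4).
#' @return energy in eps.
#' @examples
#' contact_well(5, 5, 1)    # -1 eps at the minimum
#' contact_well(5.5, 5.5, 4)  # disulfide at equilibrium: -4 eps
#' @export
contact_well <- function(r, r0, depth = 1) {
  if (any(r <= 0)) stop("distance must be positive")
  s6 <- (r0 / r)^6
  depth * (s6^2 - 2 * s6)
}

#' Rupture distance of a contact
#'
#' A contact switches off when the pair distance exceeds
#' `breakage_factor * r0 / 2^(1/6)` (3/2 of the LJ sigma by default).
#'
#' @param r0 contact equilibrium distance (Angstrom).
#' @param params a [dsb_params()].
#' @return threshold distance in Angstrom.
#' @examples
#' contact_off_threshold(5)  # ~6.68 A for bb contacts
#' @export
contact_off_threshold <- function(r0, params = dsb_params()) {
  params$breakage_factor * r0 / 2^(1 / 6)
}

#' Debye-Hueckel energy with distance-dependent permittivity
#'
#' Screened Coulomb interaction with relative permittivity growing
#' linearly with distance, `eps_r(r) = kappa_perm * r`, which turns the
#' Coulomb factor into `1/r^2`:
#' `V(r) = ke q_i q_j / (kappa_perm r^2) * exp(-r / lambda_D)`.
#'
#' @param r distance(s), Angstrom.
#' @param q_i,q_j charges in elementary units.
#' @param params a [dsb_params()].
#' @return energy in eps; zero when either charge is zero.
#' @export
debye_huckel <- function(r, q_i, q_j, params = dsb_params()) {
  if (any(r <= 0)) stop("distance must be positive")
  params$coulomb_k * q_i * q_j / (params$kappa_perm * r^2) *
    exp(-r / params$debye_length)
}

#' Wall potential
#'
#' Repulsive solid-wall term `(eps/9) (sigma/z)^9` with `sigma = 0.5` nm;
#' with `adhesive = TRUE` the quasi-adiabatically switched attractive well
#' (depth 4 eps, a full 6-12 LJ in the wall distance) is added at the
#' given activation `lambda`.
#'
#' @param z_dist distance(s) to the nearer wall, Angstrom; must be > 0.
#' @param adhesive logical; include the adhesive well?
#' @param lambda activation of the adhesive well in `[0, 1]`.
#' @param params a [dsb_params()].
#' @return energy in eps.
#' @examples
#' wall_potential(5)   # eps/9 at z = sigma
#' @export
wall_potential <- function(z_dist, adhesive = FALSE, lambda = 1,
                           params = dsb_params()) {
  if (any(z_dist <= 0)) stop("residue beyond wall: z_dist must be positive")
  sgn <- if (isTRUE(params$wall_printed_sign)) -1 else 1
  v <- sgn * (params$epsilon / 9) * (params$wall_sigma / z_dist)^9
  if (adhesive)
    v <- v + lambda * contact_well(z_dist, params$wall_adhesion_r0,
                                   params$wall_adhesion_depth)
  v
}

#' Tabulated angle and dihedral energy of a state
#'
#' Sums the tabulated bond-angle potential over all chain triples and the
#' periodic dihedral potential over all chain quads, interpolated by cubic
#' splines.
#'
#' @param state a `dsb_state`.
#' @param topology the matching [dsb_topology()].
#' @param params a [dsb_params()] carrying the tables.
#' @return named numeric vector with `angle` and `dihedral` energies (eps).
#' @export
angle_dihedral_energy <- function(state, topology, params = dsb_params()) {
  eb <- total_energy_forces(state, topology, params)$breakdown
  c(angle = unname(eb["angle"]), dihedral = unname(eb["dihedral"]))
}

#' Total potential energy and forces
#'
#' Evaluates every force-field term with minimum-image displacements for
#' the current contact registry (at its current activations): bonds,
#' tabulated angles/dihedrals, excluded volume, contact wells, Go and
#' disulfide contacts, Debye-Hueckel electrostatics and the walls.
#' `j = i + 2` pairs along a chain interact by excluded volume only.
#' Forces are the exact negative gradients of the reported total.
#'
#' @param state a `dsb_state`.
#' @param topology the matching [dsb_topology()].
#' @param params a [dsb_params()].
#' @return list with `breakdown` (named energies, eps, including `total`)
#'   and `forces` (N x 3 matrix, eps/A).
#' @export
total_energy_forces <- function(state, topology, params = dsb_params()) {
  cpp_energy_forces(state$x, unclass(state$box), unclass(topology),
                    unclass(params), state$registry)
}
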