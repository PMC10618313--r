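#' Synthetic test systems with known properties
#'
#' Deterministic generators for the objects the diagnostics are validated
#' on: gluten-like multichain systems (long Q/P/G-rich uncharged chains
#' with a configurable cysteine fraction), straight rods with closed-form
#' shape metrics, hollow bead shells with an analytically known enclosed
#' volume, interlocked open hooks with exactly one entangled pair, ideal
#' gases, and chains confined to disjoint slabs (guaranteed unentangled).
#'
#' @param kind one of `gluten_like_system`, `rod`, `hollow_shell`,
#'   `interlocked_hooks`, `ideal_gas`, `slab`.
#' @param seed integer; every generator is deterministic given its seed.
#' @param ... size parameters, see Details.
#' @details
#' * `gluten_like_system(M, L, q_frac = 0.35, p_frac = 0.15,
#'   g_frac = 0.15, cys_frac = 0.04)`: returns a topology of `M` chains
#'   of length `L`; glutamine fraction >= 30% by construction, no charged
#'   residues.
#' * `rod(n, spacing = 3.8)`: straight chain along X;
#'   `Ree = (n-1) spacing`, `Rg^2 = spacing^2 (n^2-1)/12`.
#' * `hollow_shell(inner_radius, n_shells = 1, gap = 40, bead_spacing = 3,
#'   ball_radius = 1.9, residue_radius = 3.8)`: Fibonacci-sphere bead
#'   shells whose enclosed probe volume is `4/3 pi inner_radius^3` each.
#' * `interlocked_hooks(radius = 15, spacing = 3.8)`: two open circles in
#'   orthogonal planes forming one linked pair.
#' * `ideal_gas(n, side = 60)`: uniform points in a cubic box.
#' * `slab(M = 5, L = 20, side = 150)`: wiggly chains, each confined to
#'   its own Z slab.
#' @return list with (as applicable) `x`, `topology`, `box`, and analytic
#'   reference values (`Ree`, `Rg`, `enclosed_volume_nm3`,
#'   `n_entanglements`).
#' @examples
#' rod <- generate_fixture("rod", n = 10)
#' rod$Ree  # 9 * 3.8
#' @export
generate_fixture <- function(kind, seed = 1L, ...) {
  kind <- match.arg(kind, c("gluten_like_system", "rod", "hollow_shell",
                            "interlocked_hooks", "ideal_gas", "slab"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  switch(kind,
         gluten_like_system = fixture_gluten(...),
         rod = fixture_rod(...),
         hollow_shell = fixture_shell(...),
         interlocked_hooks = fixture_hooks(...),
         ideal_gas = fixture_gas(...),
         slab = fixture_slab(...))
}

fixture_gluten <- function(M = 10, L = 50, q_frac = 0.35, p_frac = 0.15,
                           g_frac = 0.15, cys_frac = 0.04) {
  if (q_frac < 0.30) stop("glutamine fraction must stay above 30%")
  rest <- 1 - q_frac - p_frac - g_frac - cys_frac
  if (rest < 0) stop("fractions exceed 1")
  pool <- c("S", "T", "N", "A", "V", "L", "I", "F", "Y", "M")
  seqs <- vapply(seq_len(M), function(k) {
    nq <- ceiling(q_frac * L)
    np <- round(p_frac * L)
    ng <- round(g_frac * L)
    nc <- round(cys_frac * L)
    nr <- L - nq - np - ng - nc
    if (nr < 0) stop("chain too short for the requested composition")
    letters1 <- c(rep("Q", nq), rep("P", np), rep("G", ng), rep("C", nc),
                  sample(pool, nr, replace = TRUE))
    paste(sample(letters1), collapse = "")
  }, character(1))
  list(topology = dsb_topology(seqs), sequences = seqs)
}

fixture_rod <- function(n = 100, spacing = 3.8) {
  side <- max(4 * (n - 1) * spacing, 100)
  x <- cbind(side / 2 + (seq_len(n) - (n + 1) / 2) * spacing,
             side / 2, side / 2)
  list(x = x, topology = dsb_topology(paste(rep("G", n), collapse = "")),
       box = dsb_box(side, side, 0, side),
       Ree = (n - 1) * spacing,
       Rg = sqrt(spacing^2 * (n^2 - 1) / 12))
}

fibonacci_sphere <- function(n, R, centre) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(centre[1] + R * sin(phi) * cos(th),
        centre[2] + R * sin(phi) * sin(th),
        centre[3] + R * cos(phi))
}

fixture_shell <- function(inner_radius = 10, n_shells = 1, gap = 40,
                          bead_spacing = 3, ball_radius = 1.9,
                          residue_radius = 3.8) {
  R <- inner_radius + ball_radius + residue_radius
  nb <- ceiling(4 * pi * R^2 / bead_spacing^2)
  side <- max(2 * (R + 15), n_shells * gap + 2 * (R + 15))
  pts <- NULL
  for (s in seq_len(n_shells)) {
    centre <- c(side / 2, side / 2,
                (s - (n_shells + 1) / 2) * gap + side / 2)
    pts <- rbind(pts, fibonacci_sphere(nb, R, centre))
  }
  list(x = pts,
       topology = dsb_topology(rep(paste(rep("G", nb), collapse = ""),
                                   n_shells)),
       box = dsb_box(side, side, 0, side),
       enclosed_volume_nm3 = 4 / 3 * pi * inner_radius^3 / 1000,
       n_shells = n_shells)
}

open_circle <- function(R, centre, u, v, gap_angle, spacing) {
  # open circle in the plane spanned by u, v; gap centred at angle 0
  half <- gap_angle / 2
  arc <- 2 * pi - gap_angle
  n <- max(8, round(arc * R / spacing))
  th <- seq(half, 2 * pi - half, length.out = n)
  t(sapply(th, function(a)
    centre + R * cos(a) * u + R * sin(a) * v))
}

fixture_hooks <- function(radius = 15, spacing = 3.8) {
  R <- radius
  side <- 4 * R + 40
  c0 <- c(side / 2, side / 2, side / 2 - R / 2)
  # hook A: open circle in the XZ plane, gap near +X
  A <- open_circle(R, c0, c(1, 0, 0), c(0, 0, 1), 0.35, spacing)
  # hook B: open circle in the YZ plane centred one radius above, gap at
  # its top; it pierces A's disc once (at A's centre), so the pair is
  # linked
  B <- open_circle(R, c0 + c(0, 0, R), c(0, 0, 1), c(0, 1, 0), 0.35,
                   spacing)
  x <- rbind(A, B)
  top <- dsb_topology(c(paste(rep("G", nrow(A)), collapse = ""),
                        paste(rep("G", nrow(B)), collapse = "")))
  list(x = x, topology = top, box = dsb_box(side, side, 0, side),
       n_entanglements = 1L)
}

fixture_gas <- function(n = 1000, side = 60) {
  x <- cbind(runif(n) * side, runif(n) * side, runif(n) * side)
  list(x = x, box = dsb_box(side, side, 0, side))
}

fixture_slab <- function(M = 5, L = 20, side = 150, spacing = 3.8) {
  h <- side / M
  xs <- NULL
  for (c in seq_len(M)) {
    z0 <- (c - 0.5) * h
    p <- matrix(NA_real_, L, 3)
    p[1, ] <- c(runif(1, 0.2, 0.8) * side, runif(1, 0.2, 0.8) * side, z0)
    dir <- runif(1, 0, 2 * pi)
    for (i in 2:L) {
      dir <- dir + runif(1, -0.4, 0.4)
      p[i, ] <- p[i - 1, ] + spacing * c(cos(dir), sin(dir), 0) +
        c(0, 0, runif(1, -0.5, 0.5))
      p[i, 3] <- min(max(p[i, 3], z0 - 0.3 * h), z0 + 0.3 * h)
    }
    xs <- rbind(xs, p)
  }
  top <- dsb_topology(rep(paste(rep("G", L), collapse = ""), M))
  list(x = xs, topology = top, box = dsb_box(side, side, 0, side),
       n_entanglements = 0L)
}
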