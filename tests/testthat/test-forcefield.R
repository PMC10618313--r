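p0 <- dsb_params()

test_that("the bond term is harmonic with the stated constant", {
  expect_equal(bond_energy(3.8)$energy, 0)
  expect_equal(bond_energy(3.8)$force, 0)
  expect_equal(bond_energy(4.8)$energy, 50)
  expect_equal(bond_energy(2.8)$energy, 50)
})

test_that("excluded volume is the shifted LJ, zero at and past the cutoff", {
  expect_equal(excluded_volume(5), 0)
  expect_equal(excluded_volume(6), 0)
  expect_equal(excluded_volume(10), 0)
  expect_equal(excluded_volume(5 / 2^(1 / 6)), 1)
  # continuity of value and derivative at the cutoff
  h <- 1e-7
  expect_lt(excluded_volume(5 - h), 1e-10)
  d_in <- (excluded_volume(5 - h) - excluded_volume(5 - 2 * h)) / h
  expect_lt(abs(d_in), 1e-4)
  expect_error(excluded_volume(0), "positive")
})

test_that("contact wells have depth -depth at the equilibrium distance", {
  expect_equal(contact_well(5, 5, 1), -1)
  expect_equal(contact_well(6.8, 6.8, 1), -1)
  expect_equal(contact_well(5.5, 5.5, 4), -4)     # disulfide depth
  expect_lt(abs(contact_well(500, 5, 1)), 1e-10)  # decay to zero
  # r0 is the minimum
  r <- seq(4, 10, by = 0.01)
  expect_equal(r[which.min(contact_well(r, 6, 1))], 6, tolerance = 0.01)
})

test_that("the rupture threshold follows 3/2 * r0 / 2^(1/6)", {
  expect_equal(contact_off_threshold(5), 1.5 * 5 / 2^(1 / 6))
  expect_equal(round(contact_off_threshold(5), 2), 6.68)
})

test_that("Debye-Hueckel term: sign, zero charge, and 1/r^2 scaling", {
  expect_equal(debye_huckel(7, 0, 1), 0)
  expect_gt(debye_huckel(7, 1, 1), 0)
  expect_lt(debye_huckel(7, 1, -1), 0)
  r <- 6
  ratio <- debye_huckel(2 * r, 1, 1) / debye_huckel(r, 1, 1)
  expect_equal(ratio, exp(-r / p0$debye_length) / 4, tolerance = 1e-12)
})

test_that("wall term: repulsion at sigma, decay, adhesive well depth", {
  expect_equal(wall_potential(5), 1 / 9)
  expect_lt(wall_potential(60), 1e-9)
  expect_equal(wall_potential(5, adhesive = TRUE, lambda = 1) -
                 wall_potential(5), -4)
  expect_error(wall_potential(-1), "beyond wall")
  pp <- dsb_params(wall_printed_sign = TRUE)
  expect_equal(wall_potential(5, params = pp), -1 / 9)
})

test_that("flat angle/dihedral tables give zero energy and forces", {
  pf <- dsb_params(angle_table = list(x = seq(0, pi, length.out = 10),
                                      y = rep(0, 10)),
                   dihedral_table = list(x = seq(-pi, pi - 0.2,
                                                 length.out = 18),
                                         y = rep(0, 18)),
                   walls_enabled = FALSE)
  set.seed(2)
  top <- dsb_topology("GGGGGG")
  x <- rand_chain_xyz(6)
  st <- dsb_state(x, dsb_box(80, 80, 0, 80), top)
  out <- total_energy_forces(st, top, pf)
  expect_equal(out$breakdown[["angle"]], 0)
  expect_equal(out$breakdown[["dihedral"]], 0)
})

test_that("a harmonic angle table is minimal at its centre", {
  th <- seq(0, pi, length.out = 65)
  th0 <- th[33]  # grid node, so the spline passes through zero exactly
  pa <- dsb_params(angle_table = list(x = th, y = 3 * (th - th0)^2),
                   use_angle_potentials = TRUE, walls_enabled = FALSE)
  # trimer bent at exactly th0
  x <- rbind(c(40, 40, 40),
             c(43.8, 40, 40),
             c(43.8, 40, 40) + 3.8 * c(-cos(th0), sin(th0), 0))
  top <- dsb_topology("GGG")
  st <- dsb_state(x, dsb_box(80, 80, 0, 80), top)
  eb <- total_energy_forces(st, top, pa)$breakdown
  expect_lt(abs(eb[["angle"]]), 1e-9)
})

test_that("malformed angle tables are rejected", {
  expect_error(
    total_energy_forces(
      dsb_state(rand_chain_xyz(4), dsb_box(80, 80, 0, 80),
                dsb_topology("GGGG")),
      dsb_topology("GGGG"),
      dsb_params(angle_table = list(x = seq(0.5, pi, length.out = 10),
                                    y = rep(0, 10)))),
    "cover")
})

make_fd_state <- function(n = 8, seed = 1, charged = FALSE,
                          near_wall = FALSE) {
  set.seed(seed)
  seqs <- if (charged) paste(sample(c("D", "K", "E", "R"), n, TRUE),
                             collapse = "")
          else paste(sample(c("G", "Q", "S", "L"), n, TRUE), collapse = "")
  top <- dsb_topology(seqs)
  zl <- if (near_wall) c(2.5, 12) else c(20, 60)
  x <- rand_chain_xyz(n, start = c(40, 40, mean(zl)), zlim = zl)
  st <- dsb_state(x, dsb_box(80, 80, 0, 80), top)
  list(st = st, top = top)
}

test_that("analytic forces match central differences for every term", {
  configs <- 25  # per term variant; x4 variants = 100 configurations
  for (variant in 1:4) {
    for (k in seq_len(configs)) {
      seed <- 1000 * variant + k
      if (variant == 1) {
        # bonds + angles + dihedrals + excluded volume
        f <- make_fd_state(8, seed)
        params <- dsb_params(walls_enabled = FALSE)
        st <- f$st
      } else if (variant == 2) {
        # contact wells at partial activation, disulfide and go records
        f <- make_fd_state(8, seed)
        params <- dsb_params(walls_enabled = FALSE)
        st <- f$st
        st$registry <- data.frame(
          i = c(1L, 2L), j = c(5L, 7L), kind = c(1L, 4L),
          r0 = c(5, 6.1), depth = c(1, 1),
          lambda = c(0.37, 1), dir = c(1L, 0L))
      } else if (variant == 3) {
        # electrostatics between charged residues
        f <- make_fd_state(8, seed, charged = TRUE)
        params <- dsb_params(walls_enabled = FALSE)
        st <- f$st
      } else {
        # walls, repulsive and adhesive
        f <- make_fd_state(6, seed, near_wall = TRUE)
        params <- dsb_params()
        st <- f$st
        st$registry <- data.frame(i = 2L, j = -1L, kind = 7L, r0 = 5,
                                  depth = 4, lambda = 0.6, dir = 1L)
      }
      Fa <- total_energy_forces(st, f$top, params)$forces
      Fn <- fd_forces(st, f$top, params)
      expect_lt(rel_force_err(Fa, Fn), 1e-5)
    }
  }
})

test_that("energy is invariant under in-plane translation by cell vectors", {
  f <- make_fd_state(10, 77)
  params <- dsb_params(walls_enabled = FALSE)
  e0 <- total_energy_forces(f$st, f$top, params)$breakdown[["total"]]
  st2 <- f$st
  st2$x[, 1] <- st2$x[, 1] + f$st$box$Lx
  e1 <- total_energy_forces(st2, f$top, params)$breakdown[["total"]]
  expect_equal(e0, e1, tolerance = 1e-10)
})

test_that("internal forces sum to zero (Newton's third law, walls off)", {
  for (seed in 1:5) {
    f <- make_fd_state(10, seed, charged = TRUE)
    params <- dsb_params(walls_enabled = FALSE)
    Fa <- total_energy_forces(f$st, f$top, params)$forces
    expect_lt(max(abs(colSums(Fa))), 1e-8 * max(1, max(abs(Fa))))
  }
})

test_that("two isolated neutral residues beyond all cutoffs have zero energy", {
  top <- dsb_topology(c("G", "G"))
  x <- rbind(c(30, 30, 40), c(40, 30, 40))
  st <- dsb_state(x, dsb_box(80, 80, 0, 80), top)
  eb <- total_energy_forces(st, top, dsb_params(walls_enabled = FALSE))
  expect_equal(eb$breakdown[["total"]], 0)
})
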