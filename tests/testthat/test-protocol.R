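test_that("SAW initialisation: exact bonds, exclusion, no initial contacts", {
  top <- dsb_topology(c(strrep("Q", 10), strrep("G", 12)))
  p <- dsb_params()
  st <- init_saw(top, rho_start = 0.05, seed = 3, params = p)
  expect_equal(residue_density(st), 0.05, tolerance = 1e-9)
  bp <- bonded_pairs(top)
  bl <- sqrt(rowSums((st$x[bp[, 1], ] - st$x[bp[, 2], ])^2))
  # bonds are exact up to the X/Y wrap; use minimum-image lengths
  bl <- vapply(seq_len(nrow(bp)), function(k)
    sqrt(sum(minimum_image(st$x[bp[k, 1], ], st$x[bp[k, 2], ],
                           st$box)^2)), numeric(1))
  expect_equal(bl, rep(3.8, nrow(bp)), tolerance = 1e-9)
  # non-adjacent pairs respect the hard core
  cr <- chain_ranges(top)
  for (c in seq_len(nrow(cr))) {
    idx <- cr$from[c]:cr$to[c]
    for (a in idx) for (b in idx) {
      if (b > a + 1) {
        d <- sqrt(sum(minimum_image(st$x[a, ], st$x[b, ], st$box)^2))
        expect_gte(d, 4.0)
      }
    }
  }
  # chains start out of contact: no inter-chain candidates at t = 0
  cand <- eligible_contacts(st, top, p)
  inter <- cand[top$chain_id[cand$i] != top$chain_id[cand$j], ]
  expect_equal(nrow(inter), 0)
  # determinism
  st2 <- init_saw(top, rho_start = 0.05, seed = 3, params = p)
  expect_identical(st$x, st2$x)
})

test_that("squeezing reaches the target density at the stated speed", {
  top <- dsb_topology(strrep("G", 30))
  p <- dsb_params()
  st <- init_saw(top, rho_start = 0.05, seed = 1, params = p)
  # no-op when already at the target
  expect_equal(squeeze_to_density(st, top, p, 0.05)$time, st$time)
  expect_error(squeeze_to_density(st, top, p, 0.01), "below")
  # kinematics: shrinking one dimension by 1 A at 0.02 A/tau takes 50 tau
  L0 <- st$box$Lx
  rho_t <- 30 / ((L0 - 1) / 10)^3
  st1 <- squeeze_to_density(st, top, p, rho_t, speed = 0.02)
  expect_equal(st1$time - st$time, 50, tolerance = 0.01)
  expect_equal(residue_density(st1), rho_t, tolerance = 1e-3)
  expect_equal(nrow(st1$x), 30)  # residue count conserved
})

test_that("bond lengths stay near 3.8 A while squeezing at 0.02 A/tau", {
  top <- dsb_topology(c(strrep("Q", 12), strrep("G", 12)))
  p <- dsb_params()
  st <- init_saw(top, rho_start = 0.04, seed = 2, params = p)
  st <- thermalize(st, p)
  st <- squeeze_to_density(st, top, p, 0.0485, speed = 0.02,
                           frame_stride = 2000)
  bp <- bonded_pairs(top)
  for (fr in attr(st, "frames")) {
    bl <- vapply(seq_len(nrow(bp)), function(k) {
      b <- fr$box
      sqrt(sum(cpp_min_image(fr$x[bp[k, 1], ], fr$x[bp[k, 2], ],
                             b)^2))
    }, numeric(1))
    expect_true(all(abs(bl - 3.8) / 3.8 < 0.2))
  }
})

test_that("wall adhesion: no records far from walls, -4 eps at the well", {
  top <- dsb_topology("G")
  p <- dsb_params()
  box <- dsb_box(60, 60, 0, 60, adhesion = TRUE)
  far <- dsb_state(matrix(c(30, 30, 30), 1), box, top)
  far <- update_registry(far, top, p, dtau = 1)
  expect_equal(sum(far$registry$kind == 7), 0)
  near <- dsb_state(matrix(c(30, 30, 5), 1), box, top)
  near <- update_registry(near, top, p, dtau = 10)  # completes the ramp
  expect_equal(sum(near$registry$kind == 7), 1)
  eb <- total_energy_forces(near, top, p)$breakdown
  # adhesive well -4 eps plus the repulsive (eps/9)(sigma/z)^9 terms
  rep_term <- wall_potential(5) + wall_potential(55)
  expect_equal(eb[["wall"]], -4 + rep_term, tolerance = 1e-9)
})

test_that("adhesion records accumulate monotonically in a quiescent slab", {
  top <- dsb_topology(strrep("G", 8))
  p <- dsb_params(kBT = 0, use_angle_potentials = FALSE)
  x <- cbind(10 + 3.8 * (0:7), 30, seq(4.6, 5.2, length.out = 8))
  st <- dsb_state(x, dsb_box(60, 60, 0, 40), top)
  st <- enable_wall_adhesion(st)
  counts <- c()
  for (k in 1:6) {
    st <- run_segment(st, top, p, 200)
    counts <- c(counts, sum(st$registry$kind == 7))
  }
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], 0)
})

test_that("oscillation cycles deform and exactly close the cell", {
  top <- dsb_topology(c(strrep("G", 10), strrep("Q", 10)))
  p <- dsb_params()
  st <- init_saw(top, rho_start = 0.05, seed = 5, params = p)
  st <- thermalize(st, p)
  sch <- dsb_schedule(rho_target = 0.06, scale = 1 / 1000, osc_amp = 0.1,
                      n_cycles = 2)
  Lx0 <- st$box$Lx
  # shear strain peaks a quarter period in
  qtr <- run_segment(st, top, p,
                     round(sch$osc_period / 4 / p$dt),
                     motion = list(type = 2L, mode = 1L, amp = 0.1,
                                   period = sch$osc_period))
  expect_equal(qtr$box$tilt, 0.1 * st$box$Ly, tolerance = 1e-3)
  # full cycles return the cell to its initial shape
  out <- oscillate_box(st, top, p, sch)
  expect_equal(out$box$tilt, 0)
  expect_equal(out$box$Lx, Lx0, tolerance = 1e-6)
  cyc <- attr(out, "cycles")
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$mode, c("shear", "normal"))
  # zero amplitude leaves the box alone
  sch0 <- dsb_schedule(rho_target = 0.06, scale = 1 / 1000, osc_amp = 0)
  out0 <- oscillate_box(st, top, p, sch0)
  expect_equal(out0$box$Lx, Lx0)
  expect_error(dsb_schedule(rho_target = 1, osc_amp = 1.2), "amplitude")
})

test_that("the schedule scales coherently and validates its inputs", {
  s <- dsb_schedule(rho_target = 3.5, scale = 1 / 100)
  expect_equal(s$equil_tau, 2000)
  expect_equal(s$osc_period, 400)
  expect_equal(s$squeeze_speed, 2)
  expect_error(dsb_schedule(rho_target = 0.04, rho_start = 0.05),
               "below rho_target")
  expect_error(dsb_schedule(rho_target = 1, rho_start = 0.2), "0.1")
})

test_that("a density sweep is deterministic and flags single repeats", {
  fx <- generate_fixture("gluten_like_system", M = 3, L = 12, seed = 4)
  sch <- dsb_schedule(rho_target = 1, scale = 2e-5, n_cycles = 1)
  p <- dsb_params(contact_stride = 4L)
  sw1 <- density_sweep(fx$topology, c(1, 2), repeats = 1, schedule = sch,
                       params = p, base_seed = 5)
  sw2 <- density_sweep(fx$topology, c(1, 2), repeats = 1, schedule = sch,
                       params = p, base_seed = 5)
  expect_identical(sw1$runs, sw2$runs)
  expect_false(sw1$error_bars)
  expect_true(all(is.na(sw1$summary$se)))
  expect_error(density_sweep(fx$topology, 1, repeats = 0, schedule = sch),
               "repeats")
})
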