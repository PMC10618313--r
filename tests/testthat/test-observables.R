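test_that("density profiles bin, conserve counts, and follow Poisson noise", {
  box <- dsb_box(60, 60, 0, 60)
  # everything in one plane -> a single occupied bin
  x <- cbind(runif(50, 0, 60), 31, runif(50, 0, 60))
  pr <- density_profile(x, box, axis = "y", bin_width = 2)
  expect_equal(sum(pr$count > 0), 1)
  expect_equal(sum(pr$count), 50)
  expect_equal(pr$mid[pr$count > 0], 31)
  # uniform points: per-bin counts inside 5-sigma Poisson bands
  set.seed(13)
  n <- 10000
  xu <- cbind(runif(n, 0, 60), runif(n, 0, 60), runif(n, 0, 60))
  pu <- density_profile(xu, box, axis = "y", bin_width = 2)
  lam <- n / nrow(pu)
  expect_true(all(abs(pu$count - lam) < 5 * sqrt(lam)))
  expect_equal(sum(pu$count), n)
  expect_error(density_profile(xu, box, bin_width = 0), "positive")
})

test_that("g(r) is flat for an ideal gas and spikes for a fixed pair", {
  gas <- generate_fixture("ideal_gas", n = 3000, side = 60, seed = 3)
  g <- radial_distribution(gas$x, gas$box, r_max = 25, dr = 0.5)
  mid <- g$r > 3 & g$r < 25
  expect_lt(abs(mean(g$g[mid]) - 1), 0.03)
  expect_true(all(abs(g$g[mid] - 1) < 0.5))

  two <- rbind(c(30, 30, 30), c(36, 30, 30))
  g2 <- radial_distribution(two, gas$box, r_max = 20, dr = 0.2)
  expect_equal(sum(g2$count), 1)
  expect_equal(g2$r[g2$count == 1], 6.1, tolerance = 0.11)
  expect_error(radial_distribution(two, gas$box, r_max = 40), "half")
})

test_that("g(r) pair counts integrate to N(N-1)/2 for a compact cloud", {
  set.seed(14)
  box <- dsb_box(100, 100, 0, 100)
  x <- cbind(runif(80, 40, 60), runif(80, 40, 60), runif(80, 40, 60))
  g <- radial_distribution(x, box, r_max = 45, dr = 0.5)
  expect_equal(sum(g$count), 80 * 79 / 2)
})

test_that("rod shape metrics match the closed forms", {
  r <- generate_fixture("rod", n = 100)
  sm <- shape_metrics(r$x, r$topology, box = r$box)
  expect_equal(sm$Ree, r$Ree)
  expect_equal(sm$Rg, r$Rg, tolerance = 1e-12)
  expect_equal(sm$W, 1, tolerance = 1e-12)
})

test_that("shape metrics are invariant under rigid motion; W ~ 0 isotropic", {
  set.seed(15)
  n <- 4000
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3) * 10
  cloud <- sweep(u, 2, c(50, 50, 50), "+")
  top <- dsb_topology(strrep("G", n))
  sm <- shape_metrics(cloud, top)
  expect_lt(sm$W, 0.01)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  cl2 <- t(R %*% t(cloud)) + 5
  sm2 <- shape_metrics(cl2, top)
  expect_equal(sm2$Rg, sm$Rg, tolerance = 1e-10)
  expect_equal(sm2$W, sm$W, tolerance = 1e-8)
  expect_error(shape_metrics(matrix(1, 1, 3), dsb_topology("G")), ">= 2")
})

test_that("the regime classifier follows the published thresholds", {
  expect_equal(as.character(classify_regime(0)), "infinitely-dilute")
  expect_equal(as.character(classify_regime(0.5)), "dilute")
  expect_equal(as.character(classify_regime(2.0)), "intermediate")
  expect_equal(as.character(classify_regime(3.5)), "dense")
  # monotone step function over a fine grid
  rho <- seq(0, 6, by = 0.01)
  lev <- as.integer(classify_regime(rho))
  expect_true(all(diff(lev) >= 0))
  expect_error(classify_regime(-0.1), "non-negative")
  # configurable thresholds
  expect_equal(as.character(classify_regime(2, thresholds = c(0.5, 1.5))),
               "dense")
})
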