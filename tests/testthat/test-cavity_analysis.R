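test_that("an open straight chain encloses nothing", {
  n <- 10
  x <- cbind(30 + 3.8 * seq_len(n), 50, 50)
  rep <- spaceball(x, box = dsb_box(100, 100, 0, 100))
  expect_equal(rep$n_cavities, 0)
  expect_equal(rep$V_C_max, 0)
  expect_equal(rep$V_C_total, 0)
})

test_that("a hollow shell's cavity matches the enclosed-sphere volume", {
  sh <- generate_fixture("hollow_shell", inner_radius = 10)
  rep <- spaceball(sh$x, box = sh$box)
  expect_equal(rep$n_cavities, 1)
  expect_lt(abs(rep$V_C_max - sh$enclosed_volume_nm3) /
              sh$enclosed_volume_nm3, 0.15)
  expect_equal(rep$V_C_total, rep$V_C_max)
})

test_that("two disjoint shells give two cavities", {
  sh <- generate_fixture("hollow_shell", inner_radius = 8, n_shells = 2)
  rep <- spaceball(sh$x, box = sh$box)
  expect_equal(rep$n_cavities, 2)
  expect_equal(length(rep$volumes), 2)
  expect_equal(rep$V_C_max, max(rep$volumes))
  expect_equal(rep$V_C_total, sum(rep$volumes))
  expect_lt(rep$V_C_total, box_volume(sh$box) / 1000)
})

test_that("the detector agrees exactly with the voxel flood-fill oracle", {
  # small fixtures, <= ~30^3 grid: shell and a random blob
  sh <- generate_fixture("hollow_shell", inner_radius = 6, bead_spacing = 3)
  box <- dsb_box(30, 30, 10, 44)
  ctr <- c(15, 15, 27)
  x <- sweep(sh$x, 2, colMeans(sh$x)) + rep(ctr, each = nrow(sh$x))
  got <- spaceball(x, box = box, return_balls = TRUE)
  ref <- oracle_cavities(x, box)
  expect_equal(got$n_cavities, ref$n_cavities)
  expect_equal(got$volumes, ref$volumes, tolerance = 1e-12)
  gb <- got$balls[order(got$balls$x, got$balls$y, got$balls$z),
                  c("x", "y", "z")]
  rb <- ref$balls[order(ref$balls[, 1], ref$balls[, 2], ref$balls[, 3]), ,
                  drop = FALSE]
  expect_equal(unname(as.matrix(gb)), unname(rb), tolerance = 1e-9)

  set.seed(8)
  blob <- cbind(runif(40, 8, 22), runif(40, 8, 22), runif(40, 18, 36))
  g2 <- spaceball(blob, box = box, return_balls = TRUE)
  r2 <- oracle_cavities(blob, box)
  expect_equal(g2$n_cavities, r2$n_cavities)
  expect_equal(g2$volumes, r2$volumes, tolerance = 1e-12)
})

test_that("the report is invariant under translation by full cell vectors", {
  sh <- generate_fixture("hollow_shell", inner_radius = 8)
  a <- spaceball(sh$x, box = sh$box)
  x2 <- sh$x
  x2[, 1] <- x2[, 1] + sh$box$Lx
  x2[, 2] <- x2[, 2] - sh$box$Ly
  b <- spaceball(x2, box = sh$box)
  expect_equal(a$n_cavities, b$n_cavities)
  expect_equal(a$volumes, b$volumes)
})

test_that("enlarging the residue radius never grows the outside region", {
  set.seed(9)
  box <- dsb_box(40, 40, 0, 40)
  x <- cbind(runif(60, 5, 35), runif(60, 5, 35), runif(60, 8, 32))
  radii <- c(3.0, 3.8, 4.6)
  outs <- vapply(radii, function(rr)
    spaceball(x, box = box, residue_radius = rr)$n_outside, numeric(1))
  expect_true(all(diff(outs) <= 0))
})

test_that("grid rotations only remove cavity balls, never add them", {
  sh <- generate_fixture("hollow_shell", inner_radius = 8)
  v1 <- spaceball(sh$x, box = sh$box, rotations = 1)
  v3 <- spaceball(sh$x, box = sh$box, rotations = 3)
  expect_lte(v3$V_C_total, v1$V_C_total + 1e-12)
  expect_equal(v3$n_cavities, 1)  # the shell survives the intersection
})

test_that("cavity report validates its grid and box", {
  sh <- generate_fixture("hollow_shell", inner_radius = 6)
  expect_error(spaceball(sh$x, box = sh$box, spacing = 5),
               "ball diameter")
  expect_error(spaceball(sh$x,
                         box = dsb_box(30, 30, 0, 30, tilt = 4)),
               "rectangular")
})

test_that("cavity_vs_density reshapes sweep summaries (and empty input)", {
  empty <- list(summary = data.frame(rho = numeric(), var = character(),
                                     mean = numeric(), se = numeric()))
  expect_equal(nrow(cavity_vs_density(empty)), 0)
  s <- expand.grid(rho = c(1, 2), var = c("n_cavities", "V_C_max",
                                          "V_C_total"))
  s$mean <- seq_len(nrow(s))
  s$se <- 0.1
  tab <- cavity_vs_density(list(summary = s))
  expect_equal(tab$rho, c(1, 2))
  expect_true(all(c("n_cavities", "V_C_max", "V_C_total") %in% names(tab)))
})
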