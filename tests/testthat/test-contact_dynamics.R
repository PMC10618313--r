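test_that("local frames: zig-zag binormals, collinear degeneracy, termini", {
  # planar zig-zag: all binormals parallel, perpendicular to the plane
  n <- 8
  x <- cbind(3.5 * seq_len(n), 1.5 * (seq_len(n) %% 2), 40)
  top <- dsb_topology(paste(rep("G", n), collapse = ""))
  box <- dsb_box(80, 80, 0, 80)
  fr <- local_frames(x, top, box = box)
  expect_false(fr$ok[1])
  expect_false(fr$ok[n])
  inner <- 2:(n - 1)
  expect_true(all(fr$ok[inner]))
  expect_true(all(abs(abs(fr$binormal[inner, 3]) - 1) < 1e-9))
  # orthogonality and unit length
  dots <- rowSums(fr$normal[inner, ] * fr$binormal[inner, ])
  expect_lt(max(abs(dots)), 1e-9)
  expect_equal(rowSums(fr$normal[inner, ]^2), rep(1, length(inner)))

  # straight chain: all interior triples collinear
  xs <- cbind(3.8 * seq_len(n), 40, 40)
  frs <- local_frames(xs, top, box = box)
  expect_false(any(frs$ok))
})

test_that("frames are equivariant under rigid rotations", {
  set.seed(5)
  top <- dsb_topology("GGGGGGG")
  box <- dsb_box(400, 400, 0, 400)
  x <- rand_chain_xyz(7, start = c(200, 200, 200), zlim = c(50, 350))
  fr <- local_frames(x, top, box = box)
  for (k in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0),
                c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])),
                c(0, sin(th[2]), cos(th[2])))
    R <- Rz %*% Rx
    ctr <- c(200, 200, 200)
    xr <- t(R %*% (t(x) - ctr)) + rep(ctr, each = 7)
    frr <- local_frames(xr, top, box = box)
    ok <- fr$ok
    expect_equal(frr$normal[ok, ], t(R %*% t(fr$normal[ok, ])),
                 tolerance = 1e-8)
    expect_equal(frr$binormal[ok, ], t(R %*% t(fr$binormal[ok, ])),
                 tolerance = 1e-8)
  }
})

test_that("eligibility: range, aligned-binormal bb pair, slot exhaustion", {
  p <- dsb_params()
  # far apart: nothing
  far <- bb_pair_state(sep = 20)
  expect_equal(nrow(eligible_contacts(far$state, far$top, p)), 0)
  # aligned binormals at 5 A: a bb candidate between the middle beads
  near <- bb_pair_state(sep = 5)
  cand <- eligible_contacts(near$state, near$top, p)
  expect_true(any(cand$kind == "bb" & cand$i == 2 & cand$j == 5))
  # j = i + 2 within one chain is never eligible
  expect_false(any(cand$i == 1 & cand$j == 3))
  # exhausting the backbone slots of residue 2 blocks the bb candidate
  st2 <- near$state
  st2$registry <- data.frame(i = c(2L, 2L), j = c(4L, 6L),
                             kind = c(1L, 1L), r0 = 5, depth = 1,
                             lambda = 1, dir = 0L)
  cand2 <- eligible_contacts(st2, near$top, p)
  expect_false(any(cand2$kind == "bb" & cand2$i == 2))
})

test_that("activation ramps are linear and complete in exactly 10 tau", {
  p <- dsb_params()
  near <- bb_pair_state(sep = 5)
  st <- update_registry(near$state, near$top, p, dtau = 5)
  bb <- st$registry[st$registry$kind == 1, ]
  expect_equal(nrow(bb), 1)
  expect_equal(bb$lambda, 0.5)
  st <- update_registry(st, near$top, p, dtau = 4.995)
  expect_lt(st$registry$lambda[st$registry$kind == 1], 1)
  st <- update_registry(st, near$top, p, dtau = 0.005)
  expect_equal(st$registry$lambda[st$registry$kind == 1], 1)
  expect_equal(st$registry$dir[st$registry$kind == 1], 0)
})

test_that("contacts beyond the rupture threshold ramp off and vanish", {
  p <- dsb_params()
  thr <- contact_off_threshold(5)
  for (sep in c(thr - 0.02, thr + 0.02)) {
    near <- bb_pair_state(sep = 5)
    st <- update_registry(near$state, near$top, p, dtau = 10)  # lambda 1
    # pull the chains apart to 'sep'
    st$x[4:6, 3] <- st$x[4:6, 3] + (sep - 5)
    st <- update_registry(st, near$top, p, dtau = 1)
    rec <- st$registry[st$registry$kind == 1, ]
    if (sep > thr) {
      expect_equal(rec$dir, -1L)
      expect_equal(rec$lambda, 0.9)
      st <- update_registry(st, near$top, p, dtau = 9)
      expect_equal(sum(st$registry$kind == 1), 0)
    } else {
      expect_equal(rec$dir, 0L)
      expect_equal(rec$lambda, 1)
    }
  }
})

cys_cluster <- function(n_chains = 3, spread = 5.5) {
  # short GCG chains whose middle cysteines sit on a regular polygon with
  # their side chains (-normal) pointing at the polygon centre: every
  # middle pair satisfies the ss geometry
  ctr0 <- c(40, 40, 40)
  Rc <- spread / (2 * sin(pi / max(n_chains, 2)))
  x <- NULL
  for (k in seq_len(n_chains)) {
    a <- 2 * pi * (k - 1) / n_chains
    m <- ctr0 + Rc * c(cos(a), sin(a), 0)
    w <- (ctr0 - m) / sqrt(sum((ctr0 - m)^2))  # toward the centre
    e1 <- c(0, 0, 1)
    d1 <- -w * cos(70 * pi / 180) + e1 * sin(70 * pi / 180)
    d2 <- -w * cos(70 * pi / 180) - e1 * sin(70 * pi / 180)
    x <- rbind(x, m + 3.8 * d1, m, m + 3.8 * d2)
  }
  top <- dsb_topology(rep("GCG", n_chains))
  list(state = dsb_state(x, dsb_box(80, 80, 0, 80), top), top = top)
}

test_that("each cysteine holds at most one disulfide", {
  p <- dsb_params()
  f <- cys_cluster()
  st <- f$state
  for (k in 1:30) st <- update_registry(st, f$top, p, dtau = 1)
  dis <- st$registry[st$registry$kind == 5, ]
  per_res <- table(c(dis$i, dis$j))
  if (nrow(dis)) expect_true(all(per_res <= 1))
  expect_lte(attr(st$registry, "max_disulfides_per_cys"), 1)
})

test_that("no cysteines means no disulfide records", {
  p <- dsb_params()
  near <- bb_pair_state(sep = 5)
  st <- update_registry(near$state, near$top, p, dtau = 10)
  expect_equal(sum(st$registry$kind == 5), 0)
})

test_that("a ruptured disulfide frees both partners", {
  p <- dsb_params()
  f <- cys_cluster(n_chains = 2)
  st <- f$state
  for (k in 1:15) st <- update_registry(st, f$top, p, dtau = 1)
  dis <- st$registry[st$registry$kind == 5, ]
  expect_equal(nrow(dis), 1)
  expect_setequal(c(dis$i, dis$j), c(2L, 5L))
  # drag one chain far away and let the bond ramp off
  st$x[4:6, 3] <- st$x[4:6, 3] + 30
  for (k in 1:12) st <- update_registry(st, f$top, p, dtau = 1)
  expect_equal(sum(st$registry$kind == 5), 0)
  # both are eligible again once back in range
  st$x[4:6, 3] <- st$x[4:6, 3] - 30
  cand <- eligible_contacts(st, f$top, p)
  expect_true(any(cand$kind == "disulfide" & cand$i == 2 & cand$j == 5))
})

test_that("solvation rule: identity when disabled, shift above threshold", {
  top1 <- dsb_topology("Q")
  st1 <- dsb_state(matrix(c(40, 40, 40), 1), dsb_box(80, 80, 0, 80), top1)
  p_off <- dsb_params(solvation_n_t = 0)
  expect_equal(solvation_adjustment(st1, top1, p_off),
               unname(p_off$nc_ss["Q"]))
  # isolated residue: no neighbours, unchanged even with the rule on
  p_on <- dsb_params(solvation_n_t = 5)
  expect_equal(solvation_adjustment(st1, top1, p_on),
               unname(p_on$nc_ss["Q"]))
  # a residue with 8 neighbours within 7.5 A gets its limit shifted
  centre <- c(40, 40, 40)
  nb <- t(sapply(1:8, function(k) {
    a <- 2 * pi * k / 8
    centre + 6 * c(cos(a), sin(a), 0.1 * k / 8)
  }))
  topm <- dsb_topology(paste(rep("Q", 9), collapse = ""))
  stm <- dsb_state(rbind(centre, nb), dsb_box(80, 80, 0, 80), topm)
  # brute-force neighbour count confirms the fixture
  d <- sqrt(colSums((t(nb) - centre)^2))
  expect_true(all(d < 7.5))
  up <- solvation_adjustment(stm, topm, p_on)
  expect_equal(up[1], unname(p_on$nc_ss["Q"]) + 1L)
  dn <- solvation_adjustment(stm, topm,
                             dsb_params(solvation_n_t = 5,
                                        solvation_delta = -1L))
  expect_equal(dn[1], unname(p_on$nc_ss["Q"]) - 1L)
})

test_that("registry evolution is deterministic given positions", {
  p <- dsb_params()
  f <- cys_cluster()
  a <- update_registry(f$state, f$top, p, dtau = 3)
  b <- update_registry(f$state, f$top, p, dtau = 3)
  expect_identical(a$registry, b$registry)
})
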