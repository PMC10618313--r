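test_that("an isolated chain shrinks to the straight terminus segment", {
  set.seed(11)
  box <- dsb_box(300, 300, 0, 300)
  top <- dsb_topology(strrep("G", 15))
  x <- rand_chain_xyz(15, start = c(150, 150, 150), zlim = c(50, 250))
  pp <- shrink_chains(x, top, box = box, periodic = FALSE)
  expect_equal(nrow(pp[[1]]), 2)
  expect_equal(pp[[1]][1, ], unname(x[1, ]))
  expect_equal(pp[[1]][2, ], unname(x[15, ]))
  expect_true(attr(pp, "converged"))
})

test_that("far-apart chains are unentangled, with straight paths", {
  box <- dsb_box(400, 400, 0, 400)
  top <- dsb_topology(c(strrep("G", 12), strrep("G", 12)))
  set.seed(12)
  x <- rbind(rand_chain_xyz(12, start = c(100, 100, 100),
                            zlim = c(20, 380)),
             rand_chain_xyz(12, start = c(300, 300, 300),
                            zlim = c(20, 380)))
  ent <- entanglements(x, top, box = box, periodic = FALSE)
  expect_equal(ent$n_entanglements, 0)
  expect_equal(nrow(ent$kinks), 0)
  expect_true(all(vapply(ent$paths, nrow, 1L) == 2))
})

test_that("interlocked hooks are a single entangled pair with kinks", {
  h <- generate_fixture("interlocked_hooks")
  ent <- entanglements(h$x, h$topology, box = h$box, periodic = FALSE)
  expect_equal(ent$n_entanglements, 1)
  expect_equal(unname(unlist(ent$entangled_pairs[1, ])), c(1, 2))
  expect_gte(nrow(ent$kinks), 1)
  # both primitive paths keep at least one interior (kink) vertex
  expect_true(all(vapply(ent$paths, nrow, 1L) > 2))
})

test_that("a free third chain does not add entanglements", {
  h <- generate_fixture("interlocked_hooks")
  extra <- cbind(seq(5, 5 + 3.8 * 9, by = 3.8), 5, 10)
  x <- rbind(h$x, extra)
  top <- dsb_topology(c(h$topology$sequence[
    h$topology$chain_id == 1] |> paste(collapse = ""),
    paste(h$topology$sequence[h$topology$chain_id == 2], collapse = ""),
    strrep("G", 10)))
  ent <- entanglements(x, top, box = h$box, periodic = FALSE)
  expect_equal(ent$n_entanglements, 1)
})

test_that("the count is invariant under rotation and chain relabelling", {
  h <- generate_fixture("interlocked_hooks")
  ctr <- colMeans(h$x)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xr <- t(R %*% (t(h$x) - ctr)) + rep(ctr, each = nrow(h$x))
  er <- entanglements(xr, h$topology, box = h$box, periodic = FALSE)
  expect_equal(er$n_entanglements, 1)
  # relabel: second hook first
  n1 <- sum(h$topology$chain_id == 1)
  xs <- rbind(h$x[(n1 + 1):nrow(h$x), ], h$x[1:n1, ])
  tops <- dsb_topology(c(
    paste(h$topology$sequence[h$topology$chain_id == 2], collapse = ""),
    paste(h$topology$sequence[h$topology$chain_id == 1], collapse = "")))
  es <- entanglements(xs, tops, box = h$box, periodic = FALSE)
  expect_equal(es$n_entanglements, 1)
})

test_that("chains in disjoint slabs are never entangled", {
  for (seed in 1:20) {
    f <- generate_fixture("slab", seed = seed, M = 5, L = 15)
    ent <- entanglements(f$x, f$topology, box = f$box)
    expect_equal(ent$n_entanglements, 0)
  }
})

test_that("shrinking is monotone and pins the termini", {
  h <- generate_fixture("interlocked_hooks")
  ent <- entanglements(h$x, h$topology, box = h$box, periodic = FALSE)
  sl <- ent$sweep_lengths
  expect_true(all(diff(sl) <= 1e-9))
  cr <- chain_ranges(h$topology)
  for (c in 1:2) {
    expect_equal(ent$paths[[c]][1, ], unname(h$x[cr$from[c], ]))
    expect_equal(ent$paths[[c]][nrow(ent$paths[[c]]), ],
                 unname(h$x[cr$to[c], ]))
  }
})

test_that("count_entanglements re-checks already-shrunk paths", {
  h <- generate_fixture("interlocked_hooks")
  pp <- shrink_chains(h$x, h$topology, box = h$box, periodic = FALSE)
  again <- count_entanglements(pp, h$box, periodic = FALSE)
  expect_equal(again$n_entanglements, 1)
})
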