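# Shared builders and independent oracles for the test suite.

# A random open chain with the native bond length, kept away from the walls.
rand_chain_xyz <- function(n, start = c(40, 40, 40), b = 3.8,
                           zlim = c(5, 75), min_sep = 3.4) {
  x <- matrix(NA_real_, n, 3)
  x[1, ] <- start
  for (i in seq_len(n - 1)) {
    repeat {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      p <- x[i, ] + b * u
      if (p[3] <= zlim[1] || p[3] >= zlim[2]) next
      if (i > 1 &&
          min(sqrt(colSums((t(x[1:(i - 1), , drop = FALSE]) - p)^2))) <
            min_sep) next
      break
    }
    x[i + 1, ] <- p
  }
  x
}

# Brute-force minimum image: enumerate enough in-plane images to cover the
# raw displacement plus a safety margin.
brute_min_image <- function(ri, rj, box) {
  d0 <- rj - ri
  m2 <- ceiling(abs(d0[2]) / box$Ly) + 2
  m1 <- ceiling((abs(d0[1]) + (m2 + 1) * abs(box$tilt)) / box$Lx) + 2
  best <- NULL
  bn <- Inf
  for (n1 in -m1:m1) for (n2 in -m2:m2) {
    cand <- d0 + n1 * c(box$Lx, 0, 0) + n2 * c(box$tilt, box$Ly, 0)
    nc <- sum(cand[1:2]^2)
    if (nc < bn) { bn <- nc; best <- cand }
  }
  best
}

# Independent voxel flood-fill cavity oracle (no rotations, 6-adjacency),
# reconstructing the documented grid: nx = round(Lx/spacing) with adjusted
# spacings, z layers anchored at the lower wall and padded past the
# outermost residues.
oracle_cavities <- function(x, box, ball_radius = 1.9,
                            residue_radius = 3.8, spacing = 1) {
  rcap <- ball_radius + residue_radius
  nx <- max(2, round(box$Lx / spacing))
  ny <- max(2, round(box$Ly / spacing))
  sx <- box$Lx / nx; sy <- box$Ly / ny; sz <- spacing
  zmin <- min(x[, 3]); zmax <- max(x[, 3])
  pad <- rcap + 2 * spacing
  z0 <- box$zlo - ceiling((box$zlo - (zmin - pad)) / sz) * sz
  nz <- max(3, ceiling((zmax + pad - z0) / sz) + 1)
  gx <- (seq_len(nx) - 1) * sx
  gy <- (seq_len(ny) - 1) * sy
  gz <- z0 + (seq_len(nz) - 1) * sz
  occ <- array(FALSE, c(nx, ny, nz))
  for (a in seq_len(nrow(x))) {
    px <- x[a, 1] %% box$Lx
    py <- x[a, 2] %% box$Ly
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      dx <- gx[i] - px; dx <- dx - round(dx / box$Lx) * box$Lx
      dy <- gy[j] - py; dy <- dy - round(dy / box$Ly) * box$Ly
      r2xy <- dx^2 + dy^2
      if (r2xy > rcap^2) next
      dzmax <- sqrt(rcap^2 - r2xy)
      kk <- which(abs(gz - x[a, 3]) < dzmax)
      occ[i, j, kk] <- TRUE
    }
  }
  lab <- array(2L, c(nx, ny, nz))  # 0 occ, 1 outside, 2 interior
  lab[occ] <- 0L
  queue <- NULL
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in c(1L, nz)) {
    if (lab[i, j, k] == 2L) {
      lab[i, j, k] <- 1L
      queue <- rbind(queue, c(i, j, k))
    }
  }
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  while (!is.null(queue) && nrow(queue)) {
    cur <- queue[nrow(queue), ]
    queue <- queue[-nrow(queue), , drop = FALSE]
    for (q in 1:6) {
      i <- (cur[1] + nb[q, 1] - 1) %% nx + 1
      j <- (cur[2] + nb[q, 2] - 1) %% ny + 1
      k <- cur[3] + nb[q, 3]
      if (k < 1 || k > nz) next
      if (lab[i, j, k] == 2L) {
        lab[i, j, k] <- 1L
        queue <- rbind(queue, c(i, j, k))
      }
    }
  }
  # components of the interior
  comp <- array(0L, c(nx, ny, nz))
  ncomp <- 0L
  sizes <- integer(0)
  idx <- which(lab == 2L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (comp[idx[r, 1], idx[r, 2], idx[r, 3]] > 0L) next
    ncomp <- ncomp + 1L
    sz_c <- 0L
    queue <- idx[r, , drop = FALSE]
    comp[idx[r, 1], idx[r, 2], idx[r, 3]] <- ncomp
    while (nrow(queue)) {
      cur <- queue[nrow(queue), ]
      queue <- queue[-nrow(queue), , drop = FALSE]
      sz_c <- sz_c + 1L
      for (q in 1:6) {
        i <- (cur[1] + nb[q, 1] - 1) %% nx + 1
        j <- (cur[2] + nb[q, 2] - 1) %% ny + 1
        k <- cur[3] + nb[q, 3]
        if (k < 1 || k > nz) next
        if (lab[i, j, k] == 2L && comp[i, j, k] == 0L) {
          comp[i, j, k] <- ncomp
          queue <- rbind(queue, c(i, j, k))
        }
      }
    }
    sizes <- c(sizes, sz_c)
  }
  ball_xyz <- NULL
  if (nrow(idx)) {
    idx <- which(lab == 2L, arr.ind = TRUE)
    ball_xyz <- cbind(gx[idx[, 1]], gy[idx[, 2]], gz[idx[, 3]])
  }
  list(n_cavities = ncomp,
       volumes = sort(sizes, decreasing = TRUE) * sx * sy * sz / 1000,
       balls = ball_xyz)
}

# Finite-difference gradient of the total energy at fixed registry.
fd_forces <- function(state, top, params, h = 1e-5) {
  n <- nrow(state$x)
  Fn <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) for (q in 1:3) {
    sp <- state; sp$x[i, q] <- sp$x[i, q] + h
    sm <- state; sm$x[i, q] <- sm$x[i, q] - h
    Fn[i, q] <- -(total_energy_forces(sp, top, params)$breakdown[["total"]] -
                  total_energy_forces(sm, top, params)$breakdown[["total"]]) /
      (2 * h)
  }
  Fn
}

rel_force_err <- function(Fa, Fn) {
  max(abs(Fa - Fn)) / max(1, max(abs(Fn)))
}

# Two short zig-zag chains whose middle beads satisfy the backbone
# (binormal) alignment criterion at bb contact range.
bb_pair_state <- function(sep = 5, params = dsb_params()) {
  zig <- function(z) rbind(c(-3.5, -1.5, z), c(0, 0, z), c(3.5, -1.5, z))
  x <- rbind(zig(40), zig(40 + sep))
  top <- dsb_topology(c("GGG", "GGG"))
  box <- dsb_box(100, 100, 0, 80)
  list(state = dsb_state(x + rep(c(50, 50, 0), each = 6), box, top),
       top = top)
}
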