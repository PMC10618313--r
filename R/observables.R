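#' Residue density profile along an axis
#'
#' Histogram of residue counts along one box axis for a single frame
#' (averaging over many frames washes the profiles out because the cavity
#' positions move).
#'
#' @param state a `dsb_state` or N x 3 matrix with `box`.
#' @param box a [dsb_box()] when needed.
#' @param axis "x", "y" or "z".
#' @param bin_width bin width (A), default 2.
#' @return data frame with bin `mid` (A) and residue `count`; counts sum
#'   to the number of residues.
#' @export
density_profile <- function(state, box = NULL, axis = "y", bin_width = 2) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (inherits(state, "dsb_state")) {
    x <- state$x
    box <- state$box
  } else x <- as.matrix(state)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  ext <- switch(ax, box$Lx, box$Ly, box$zhi - box$zlo)
  orig <- if (ax == 3) box$zlo else 0
  v <- x[, ax] - orig
  if (ax != 3) v <- v %% ext
  edges <- seq(0, ext, by = bin_width)
  if (edges[length(edges)] < ext) edges <- c(edges, ext)
  ct <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                 nbins = length(edges) - 1L)
  data.frame(mid = orig + (edges[-length(edges)] + edges[-1]) / 2,
             count = ct)
}

#' Radial distribution function
#'
#' Standard pair-count g(r) with minimum-image distances.  The ideal-gas
#' normalisation is corrected for the finite slab extent in Z (the shell
#' area fraction inside the walls is averaged over the actual residue
#' heights), so a uniform gas gives g = 1 up to sampling noise.
#'
#' @param state a `dsb_state` or N x 3 matrix with `box`.
#' @param box a [dsb_box()] when needed.
#' @param r_max largest distance (A); must be below half the smaller
#'   in-plane cell extent.
#' @param dr bin width (A); 0.2 A resolves the bb (5 A) and bs (6.8 A)
#'   contact peaks.
#' @return data frame with `r` (bin centre, A), `g`, and raw pair `count`.
#' @export
radial_distribution <- function(state, box = NULL, r_max = NULL,
                                dr = 0.2) {
  if (inherits(state, "dsb_state")) {
    x <- state$x
    box <- state$box
  } else x <- as.matrix(state)
  lim <- min(box$Lx, box$Ly) / 2
  if (is.null(r_max)) r_max <- lim * 0.99
  if (r_max > lim)
    stop("r_max must be below half the smallest periodic cell extent")
  n <- nrow(x)
  H <- box$zhi - box$zlo
  rho <- n / (box$Lx * box$Ly * H)
  # minimum-image pair distances
  dx <- outer(x[, 1], x[, 1], "-")
  dy <- outer(x[, 2], x[, 2], "-")
  dz <- outer(x[, 3], x[, 3], "-")
  s2 <- dy / box$Ly
  s1 <- (dx - s2 * box$tilt) / box$Lx
  s1 <- s1 - round(s1)
  s2 <- s2 - round(s2)
  ddx <- s1 * box$Lx + s2 * box$tilt
  ddy <- s2 * box$Ly
  r <- sqrt(ddx^2 + ddy^2 + dz^2)
  r <- r[upper.tri(r)]
  edges <- seq(0, r_max + dr, by = dr)
  mids <- edges[-length(edges)] + dr / 2
  ct <- tabulate(findInterval(r[r < max(edges)], edges,
                              rightmost.closed = FALSE),
                 nbins = length(mids))
  # slab-corrected ideal shell counts, averaged over actual heights
  z <- x[, 3] - box$zlo
  frac <- vapply(mids, function(rr) {
    mean((pmin(rr, z) + pmin(rr, H - z)) / (2 * rr))
  }, numeric(1))
  ideal <- 0.5 * n * rho * 4 * pi * mids^2 * dr * frac
  keep <- mids <= r_max
  data.frame(r = mids[keep], g = ifelse(ideal[keep] > 0,
                                        ct[keep] / ideal[keep], 0),
             count = ct[keep])
}

#' Chain shape metrics
#'
#' Per-chain end-to-end distance, radius of gyration and asphericity from
#' the gyration tensor.  With eigenvalues `l1 >= l2 >= l3` and
#' `tr = l1 + l2 + l3`, the asphericity is the relative shape anisotropy
#' `W = ((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / (2 tr^2)`, 0 for an
#' isotropic cloud and 1 for a straight rod.
#'
#' @param state a `dsb_state` or N x 3 matrix (chains unwrapped through
#'   the periodic boundary automatically).
#' @param topology the matching [dsb_topology()].
#' @param box a [dsb_box()] when `state` is a bare matrix.
#' @return data frame with one row per chain: `chain`, `n`, `Ree`, `Rg`,
#'   `W`.
#' @export
shape_metrics <- function(state, topology, box = NULL) {
  if (inherits(state, "dsb_state")) {
    x <- state$x
    box <- state$box
  } else x <- as.matrix(state)
  if (!is.null(box)) x <- unwrap_chains(x, topology, box)
  cr <- chain_ranges(topology)
  out <- lapply(seq_len(nrow(cr)), function(c) {
    p <- x[cr$from[c]:cr$to[c], , drop = FALSE]
    n <- nrow(p)
    if (n < 2) stop("chain length must be >= 2")
    ree <- sqrt(sum((p[n, ] - p[1, ])^2))
    q <- sweep(p, 2, colMeans(p))
    S <- crossprod(q) / n
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    tr <- sum(ev)
    W <- if (tr > 0)
      ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[3] - ev[1])^2) /
        (2 * tr^2) else 0
    data.frame(chain = c, n = n, Ree = ree, Rg = sqrt(tr), W = W)
  })
  do.call(rbind, out)
}

#' Classify the residue-density regime
#'
#' The four regimes of a dense implicit-solvent protein system:
#' infinitely dilute (isolated chains, rho = 0), dilute (freely diffusing
#' chains, rho < 1 nm^-3), intermediate (an interconnected network with
#' large cavities, 1--3 nm^-3) and dense (homogeneous, many small
#' cavities, rho > 3 nm^-3).  The thresholds hold for long, sticky,
#' essentially uncharged chains and are configurable for other systems.
#'
#' @param rho residue density (nm^-3), vectorised; must be >= 0.
#' @param thresholds dilute/intermediate and intermediate/dense
#'   boundaries (nm^-3).
#' @return factor with levels infinitely-dilute, dilute, intermediate,
#'   dense.
#' @examples
#' classify_regime(c(0, 0.5, 2, 3.5))
#' @export
classify_regime <- function(rho, thresholds = c(1, 3)) {
  if (any(rho < 0)) stop("density must be non-negative")
  stopifnot(length(thresholds) == 2, diff(thresholds) > 0)
  lab <- c("infinitely-dilute", "dilute", "intermediate", "dense")
  idx <- ifelse(rho == 0, 1L,
         ifelse(rho < thresholds[1], 2L,
         ifelse(rho <= thresholds[2], 3L, 4L)))
  factor(lab[idx], levels = lab)
}
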