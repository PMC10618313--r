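#' Simulation schedule
#'
#' The full protocol: self-avoiding-walk initialisation at a dilute
#' density, a first equilibration, quasi-static squeezing at 0.02 A/tau to
#' the target density, a second equilibration, switching on wall adhesion
#' (depth 4 eps), a third equilibration, and periodic box deformation with
#' period 40,000 tau alternating shear and normal strain.
#'
#' A single `scale` factor compresses the whole schedule coherently for
#' desk-scale work: equilibration spans and the oscillation period are
#' multiplied by `scale` and the squeeze speed divided by it, so the
#' protocol keeps its shape while every stage shortens.
#'
#' @param rho_target target residue density (nm^-3).
#' @param rho_start initial dilute density (< 0.1 nm^-3).
#' @param scale schedule compression factor (1 = the full protocol).
#' @param squeeze_speed box-edge shrink speed before scaling (A/tau).
#' @param equil_tau equilibration span before scaling (tau).
#' @param osc_period oscillation period before scaling (tau).
#' @param osc_amp strain amplitude (fraction; applied to shear tilt and
#'   normal strain).
#' @param n_cycles number of deformation cycles (alternating shear and
#'   normal strain).
#' @return An object of class `dsb_schedule` with effective (scaled)
#'   spans.
#' @export
dsb_schedule <- function(rho_target, rho_start = 0.05, scale = 1,
                         squeeze_speed = 0.02, equil_tau = 200000,
                         osc_period = 40000, osc_amp = 0.1, n_cycles = 2) {
  if (rho_start >= 0.1) stop("rho_start must be below 0.1 nm^-3")
  if (rho_start >= rho_target) stop("rho_start must be below rho_target")
  if (squeeze_speed <= 0 || osc_period <= 0 || scale <= 0)
    stop("speeds, periods and scale must be positive")
  if (osc_amp < 0 || osc_amp >= 1)
    stop("oscillation amplitude must be in [0, 1)")
  s <- list(rho_target = rho_target, rho_start = rho_start, scale = scale,
            squeeze_speed = squeeze_speed / scale,
            equil_tau = equil_tau * scale,
            osc_period = osc_period * scale,
            osc_amp = osc_amp, n_cycles = as.integer(n_cycles))
  class(s) <- "dsb_schedule"
  s
}

#' @export
print.dsb_schedule <- function(x, ...) {
  cat(sprintf(
    "schedule: rho %.3g -> %.3g nm^-3, squeeze %.3g A/tau, equil %g tau,\n",
    x$rho_start, x$rho_target, x$squeeze_speed, x$equil_tau))
  cat(sprintf("  oscillation period %g tau, amplitude %g, %d cycle(s) (scale %g)\n",
              x$osc_period, x$osc_amp, x$n_cycles, x$scale))
  invisible(x)
}

#' Initialise chains as self-avoiding random walks
#'
#' Each chain grows with bond length 3.8 A and hard-core exclusion between
#' non-adjacent beads; chains are placed so no inter-chain pair is within
#' contact-capture range at t = 0.  The box is cubic at the dilute start
#' density with solid walls in Z.
#'
#' @param topology a [dsb_topology()].
#' @param rho_start starting density (nm^-3, below 0.1).
#' @param seed integer; both the placement and the simulation RNG derive
#'   from it.
#' @param params a [dsb_params()].
#' @param min_self minimum distance between non-adjacent beads of one
#'   chain (A).
#' @param min_inter minimum distance between beads of different chains
#'   (A), beyond every contact capture range.
#' @param max_restart placement retries before giving up.
#' @return a thermalised `dsb_state`.
#' @export
init_saw <- function(topology, rho_start = 0.05, seed = 1L,
                     params = dsb_params(), min_self = 4.0,
                     min_inter = 9.0, max_restart = 200L) {
  if (rho_start >= 0.1) stop("rho_start must be below 0.1 nm^-3")
  side <- box_side_for_density(topology$n_residues, rho_start) * 10
  box <- dsb_box(side, side, 0, side)
  zmargin <- 3
  b <- params$r_bond
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  cr <- chain_ranges(topology)
  x <- matrix(NA_real_, topology$n_residues, 3)
  placed <- matrix(numeric(0), 0, 3)
  clash <- function(p, pool, dmin) {
    if (!nrow(pool)) return(FALSE)
    for (k in seq_len(nrow(pool))) {
      d <- cpp_min_image(pool[k, ], p, unclass(box))
      if (sum(d^2) < dmin^2) return(TRUE)
    }
    FALSE
  }
  for (c in seq_len(nrow(cr))) {
    len <- cr$to[c] - cr$from[c] + 1L
    done <- FALSE
    for (restart in seq_len(max_restart)) {
      pts <- matrix(NA_real_, len, 3)
      pts[1, ] <- c(runif(1) * side, runif(1) * side,
                    zmargin + runif(1) * (side - 2 * zmargin))
      if (clash(pts[1, ], placed, min_inter)) next
      ok <- TRUE
      for (i in seq_len(len - 1L)) {
        good <- FALSE
        for (try in 1:80) {
          u <- rnorm(3)
          u <- u / sqrt(sum(u^2))
          p <- pts[i, ] + b * u
          if (p[3] < zmargin || p[3] > side - zmargin) next
          prev <- if (i >= 2) pts[seq_len(i - 1L), , drop = FALSE]
                  else matrix(numeric(0), 0, 3)
          if (clash(p, prev, min_self)) next
          if (clash(p, placed, min_inter)) next
          pts[i + 1L, ] <- p
          good <- TRUE
          break
        }
        if (!good) { ok <- FALSE; break }
      }
      if (ok) {
        x[cr$from[c]:cr$to[c], ] <- pts
        placed <- rbind(placed, pts)
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("chain placement failed; lower rho_start or min_inter")
  }
  # wrap into the primary cell in X/Y
  x[, 1] <- x[, 1] %% side
  x[, 2] <- x[, 2] %% side
  st <- dsb_state(x, box, topology, seed = seed)
  thermalize(st, params)
}

#' Squeeze the box to a target density
#'
#' Shrinks every box dimension at the given speed while the dynamics run
#' (fractional coordinates rescaled in the periodic plane, walls moved in
#' Z), stopping when the residue density reaches the target.  The default
#' speed is slow enough for the system to stay quasi-static.
#'
#' @param state a `dsb_state`.
#' @param topology the matching [dsb_topology()].
#' @param params a [dsb_params()].
#' @param rho_target target density (nm^-3).
#' @param speed edge shrink speed (A/tau).
#' @param frame_stride optional trajectory collection (steps).
#' @return the squeezed state (density within 0.1% of the target).
#' @export
squeeze_to_density <- function(state, topology, params = dsb_params(),
                               rho_target, speed = 0.02,
                               frame_stride = 0L) {
  rho <- residue_density(state)
  if (rho_target < rho * (1 - 1e-9))
    stop("target density below the current density")
  if (abs(rho_target - rho) / rho_target < 1e-9) return(state)
  n <- nrow(state$x)
  Lt <- (n / rho_target)^(1 / 3) * 10
  b <- state$box
  dmax <- max(b$Lx - Lt, b$Ly - Lt, (b$zhi - b$zlo) - Lt, 0)
  n_steps <- ceiling(dmax / speed / params$dt)
  motion <- list(type = 1L, rate = speed, target_Lx = Lt, target_Ly = Lt,
                 target_gap = Lt)
  state <- run_segment(state, topology, params, n_steps, motion = motion,
                       frame_stride = frame_stride)
  stopifnot(abs(residue_density(state) - rho_target) / rho_target < 1e-3)
  state
}

#' Switch on wall adhesion
#'
#' Makes the attractive wall wells (depth 4 eps) available; individual
#' residues near a wall then acquire adhesion records that switch on
#' quasi-adiabatically like any other contact.
#'
#' @param state a `dsb_state`.
#' @return the state with adhesive walls enabled.
#' @export
enable_wall_adhesion <- function(state) {
  state$box$adhesion <- TRUE
  state
}

#' Oscillatory box deformation
#'
#' Runs sinusoidal deformation cycles of the stated period, alternating
#' shear (the in-plane cell tilts into a parallelepiped) and normal strain
#' (volume-preserving in-plane stretch), with an affine remap of the
#' periodic plane each step.  Each full cycle returns the cell to its
#' initial shape.
#'
#' @param state a `dsb_state` (adhesion typically already on).
#' @param topology the matching [dsb_topology()].
#' @param params a [dsb_params()].
#' @param schedule a [dsb_schedule()] (period, amplitude, cycle count).
#' @param observables function(state) returning a named numeric vector,
#'   sampled at the end of every cycle; default records the biggest-cavity
#'   volume.
#' @param modes cycle order; recycled over `n_cycles`.
#' @return the deformed state with a per-cycle observable table attached
#'   as `attr(, "cycles")`.
#' @export
oscillate_box <- function(state, topology, params = dsb_params(),
                          schedule, observables = NULL,
                          modes = c("shear", "normal")) {
  amp <- schedule$osc_amp
  if (amp >= 1) stop("amplitude would degenerate the cell")
  if (amp == 0 || schedule$n_cycles < 1) {
    attr(state, "cycles") <- data.frame()
    return(state)
  }
  steps_per_cycle <- round(schedule$osc_period / params$dt)
  rows <- list()
  for (k in seq_len(schedule$n_cycles)) {
    mode <- modes[(k - 1L) %% length(modes) + 1L]
    motion <- list(type = 2L, mode = if (mode == "shear") 1L else 2L,
                   amp = amp, period = schedule$osc_period)
    state <- run_segment(state, topology, params, steps_per_cycle,
                         motion = motion)
    # numerical sin(2*pi) residue: snap the cell shape exactly closed
    if (mode == "shear") state$box$tilt <- round(state$box$tilt, 9)
    obs <- if (is.null(observables)) {
      cav <- spaceball(state)
      c(V_C_max = cav$V_C_max, n_cavities = cav$n_cavities)
    } else observables(state)
    rows[[k]] <- data.frame(cycle = k, mode = mode, time = state$time,
                            t(obs))
  }
  attr(state, "cycles") <- do.call(rbind, rows)
  state
}

#' Run the full simulation protocol at one density
#'
#' SAW initialisation, equilibration, squeeze to the target density,
#' second equilibration, wall adhesion, third equilibration, oscillatory
#' deformation.
#'
#' @param topology a [dsb_topology()].
#' @param schedule a [dsb_schedule()].
#' @param params a [dsb_params()].
#' @param seed integer seed.
#' @param verbose print stage progress.
#' @return list with the final `state`, the per-cycle table `cycles`, and
#'   a `stages` data frame of stage end times.
#' @export
run_protocol <- function(topology, schedule, params = dsb_params(),
                         seed = 1L, verbose = FALSE) {
  eq_steps <- round(schedule$equil_tau / params$dt)
  say <- function(...) if (verbose) message(sprintf(...))
  stages <- list()
  mark <- function(st, name) {
    stages[[length(stages) + 1L]] <<- data.frame(stage = name,
                                                 time = st$time,
                                                 rho = residue_density(st))
  }
  st <- init_saw(topology, schedule$rho_start, seed, params)
  mark(st, "init")
  say("equilibration 1 (%d steps)", eq_steps)
  st <- run_segment(st, topology, params, eq_steps)
  mark(st, "equil1")
  say("squeeze to rho = %g", schedule$rho_target)
  st <- squeeze_to_density(st, topology, params, schedule$rho_target,
                           speed = schedule$squeeze_speed)
  mark(st, "squeeze")
  st <- run_segment(st, topology, params, eq_steps)
  mark(st, "equil2")
  st <- enable_wall_adhesion(st)
  st <- run_segment(st, topology, params, eq_steps)
  mark(st, "equil3")
  say("oscillations (%d cycles)", schedule$n_cycles)
  st <- oscillate_box(st, topology, params, schedule)
  cycles <- attr(st, "cycles")
  mark(st, "oscillate")
  list(state = st, cycles = cycles, stages = do.call(rbind, stages))
}

measure_run <- function(state, topology, params) {
  cav <- spaceball(state)
  ent <- entanglements(state, topology)
  sm <- shape_metrics(state, topology)
  c(n_cavities = cav$n_cavities, V_C_max = cav$V_C_max,
    V_C_total = cav$V_C_total, n_entanglements = ent$n_entanglements,
    Ree = mean(sm$Ree), Rg = mean(sm$Rg), W = mean(sm$W))
}

free_chain_metrics <- function(topology, params, seed, equil_tau) {
  # the density-zero reference: a single chain, dilute, no walls adhesion
  sub <- dsb_topology(paste(topology$sequence[
    seq_len(topology$chain_lengths[1])], collapse = ""))
  st <- init_saw(sub, rho_start = 0.001, seed = seed, params = params)
  st <- run_segment(st, sub, params, round(equil_tau / params$dt))
  sm <- shape_metrics(st, sub)
  c(n_cavities = NA, V_C_max = NA, V_C_total = NA, n_entanglements = NA,
    Ree = mean(sm$Ree), Rg = mean(sm$Rg), W = mean(sm$W))
}

#' Density sweep
#'
#' Runs the full protocol at each density with several random repeats and
#' collects the end-of-run diagnostics: cavity count and volumes,
#' entanglement count, and chain shape metrics.  A density of 0 denotes
#' the infinitely dilute reference (a single free chain).
#'
#' @param topology a [dsb_topology()].
#' @param rho_list densities to sweep (nm^-3; 0 allowed).
#' @param repeats independent repeats per density (>= 1; with a single
#'   repeat the error bars are flagged absent).
#' @param schedule a [dsb_schedule()]; its `rho_target` is replaced per
#'   density.
#' @param params a [dsb_params()].
#' @param base_seed seeds are `base_seed + 1000 * density index + repeat`.
#' @param verbose print progress.
#' @return An object of class `dsb_sweep`: list with per-run `runs` and
#'   aggregated `summary` (mean and standard error per density).
#' @export
density_sweep <- function(topology, rho_list, repeats = 3,
                          schedule, params = dsb_params(),
                          base_seed = 1L, verbose = FALSE) {
  if (repeats < 1) stop("repeats must be >= 1")
  rows <- list()
  for (di in seq_along(rho_list)) {
    rho <- rho_list[di]
    for (rep in seq_len(repeats)) {
      seed <- as.integer(base_seed + 1000L * di + rep)
      if (verbose) message(sprintf("rho = %g, repeat %d", rho, rep))
      m <- if (rho == 0) {
        free_chain_metrics(topology, params, seed, schedule$equil_tau)
      } else {
        sch <- schedule
        sch$rho_target <- rho
        pr <- run_protocol(topology, sch, params, seed = seed)
        measure_run(pr$state, topology, params)
      }
      rows[[length(rows) + 1L]] <- data.frame(rho = rho, repeat_ = rep,
                                              seed = seed, t(m))
    }
  }
  runs <- do.call(rbind, rows)
  vars <- setdiff(names(runs), c("rho", "repeat_", "seed"))
  agg <- lapply(vars, function(v) {
    mu <- tapply(runs[[v]], runs$rho, mean)
    se <- tapply(runs[[v]], runs$rho,
                 function(z) if (length(z) > 1) sd(z) / sqrt(length(z))
                             else NA_real_)
    data.frame(rho = as.numeric(names(mu)), var = v,
               mean = as.numeric(mu), se = as.numeric(se))
  })
  out <- list(runs = runs, summary = do.call(rbind, agg),
              repeats = repeats,
              error_bars = repeats > 1)
  class(out) <- "dsb_sweep"
  out
}

#' @export
print.dsb_sweep <- function(x, ...) {
  cat(sprintf("density sweep: %d run(s) over rho = {%s} nm^-3\n",
              nrow(x$runs), paste(unique(x$runs$rho), collapse = ", ")))
  if (!x$error_bars)
    cat("  single repeat: no error bars\n")
  print(x$summary[x$summary$var %in% c("V_C_max", "n_cavities", "Rg"), ])
  invisible(x)
}

#' @export
plot.dsb_sweep <- function(x, vars = c("V_C_max", "n_cavities",
                                       "n_entanglements", "Rg"), ...) {
  s <- x$summary[x$summary$var %in% vars & x$summary$rho > 0, ]
  op <- graphics::par(mfrow = c(ceiling(length(vars) / 2), 2),
                      mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    d <- s[s$var == v, ]
    graphics::plot(d$rho, d$mean, type = "b", xlab = expression(rho ~
                   (nm^-3)), ylab = v, ...)
    if (any(is.finite(d$se)))
      graphics::arrows(d$rho, d$mean - d$se, d$rho, d$mean + d$se,
                       angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
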