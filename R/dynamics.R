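#' One Langevin integration step
#'
#' Advances the state by one `dt` under
#' `m r'' = F - gamma r' + Gamma`, with the thermal white noise of
#' variance `sigma^2 = 2 gamma kBT` as the only thermostat.  The
#' discretisation is the BAOAB splitting, whose Ornstein-Uhlenbeck
#' sub-step damps velocities by exactly `exp(-gamma dt / m)`; with
#' `gamma = 2 m / tau` the dynamics are overdamped.  Deterministic given
#' the state's RNG.
#'
#' @param state a `dsb_state`.
#' @param topology the matching [dsb_topology()].
#' @param params a [dsb_params()].
#' @return the advanced state.
#' @export
langevin_step <- function(state, topology, params = dsb_params()) {
  run_segment(state, topology, params, n_steps = 1L)
}

#' Run a dynamics segment
#'
#' Repeatedly evaluates forces, maintains the contact registry (every
#' `contact_stride` steps), and advances the Langevin integrator, with
#' optional imposed box kinematics and frame collection.  Identical seeds
#' give bitwise-identical trajectories.
#'
#' @param state a `dsb_state`.
#' @param topology the matching [dsb_topology()].
#' @param params a [dsb_params()].
#' @param n_steps number of `dt` steps (200 per tau).
#' @param motion internal box-kinematics descriptor (used by the protocol
#'   stage drivers); `NULL` for a static box.
#' @param frame_stride collect a trajectory frame every this many steps
#'   (0 = none).
#' @param collect_registry include a registry snapshot in each frame.
#' @return the advanced state; collected frames (list of `x`, `box`,
#'   `time`) are attached as `attr(, "frames")`, and the largest number of
#'   disulfides simultaneously held by any cysteine during the segment as
#'   `attr(, "max_disulfides_per_cys")`.
#' @export
run_segment <- function(state, topology, params = dsb_params(),
                        n_steps, motion = NULL, frame_stride = 0L,
                        collect_registry = FALSE) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (n_steps == 0L) return(state)
  if (is.null(motion)) motion <- list(type = 0L)
  out <- cpp_run_segment(state$x, state$v, unclass(state$box),
                         state$registry, unclass(topology),
                         unclass(params), n_steps, motion,
                         as.integer(frame_stride), state$rng,
                         state$time, isTRUE(collect_registry))
  state$x <- out$x
  state$v <- out$v
  b <- out$box
  state$box <- dsb_box(b$Lx, b$Ly, b$zlo, b$zhi, tilt = b$tilt,
                       adhesion = b$adhesion)
  state$registry <- out$registry
  state$rng <- out$rng
  state$time <- out$time
  attr(state, "frames") <- out$frames
  attr(state, "max_disulfides_per_cys") <- out$max_disulfides_per_cys
  state
}
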