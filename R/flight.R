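# Closed-loop flight: the lateral/height/speed controller and the corridor
# trial driver.

#' Flight controller parameters
#'
#' The corridor controller turns the three smoothed subregion outputs into
#' per-control-step pose changes:
#' \deqn{\Delta X = sgn(S_L, S_R) (\max(S_L, S_R) - T_X) / 2.4}
#' \deqn{\Delta Z = (S_C - T_Z) / 18}
#' \deqn{\Delta V = -(S_L + S_R - T_V) / 2.4}
#' with `sgn(A, B)` equal to +1 for `A > B`, -1 for `A < B` and 0 on a tie.
#' The lateral rule moves away from the stronger-flow (nearer) wall, the
#' height rule servoes ventral flow to its setpoint, and the speed rule
#' holds total lateral flow at `T_V`. The velocity setpoint is taken as
#' twice the horizontal one, `T_V = 2 T_X`. Deltas are applied once per
#' `control_dt`, a deliberately coarser interval than the 0.1 ms neural
#' step: applied every neural step the printed divisors would produce
#' physically absurd accelerations.
#'
#' @param t_x,t_z,t_v Setpoints in detector-output units (defaults 1.0, 0.5,
#'   2.0).
#' @param div_x,div_z,div_v Output scalings (defaults 2.4, 18, 2.4).
#' @param control_dt Control interval in ms (default 10); must be a multiple
#'   of the simulation step.
#' @param clamp_margin Minimum distance in cm kept from every corridor
#'   surface when clamping the pose (default 0.5).
#' @return An object of class `controller_params`.
#' @export
controller_params <- function(t_x = 1.0, t_z = 0.5, t_v = 2 * t_x,
                              div_x = 2.4, div_z = 18.0, div_v = 2.4,
                              control_dt = 10, clamp_margin = 0.5) {
  if (div_x <= 0 || div_z <= 0 || div_v <= 0)
    stop("controller divisors must be positive")
  if (control_dt <= 0) stop("`control_dt` must be positive (ms)")
  structure(list(t_x = t_x, t_z = t_z, t_v = t_v, div_x = div_x,
                 div_z = div_z, div_v = div_v, control_dt = control_dt,
                 clamp_margin = clamp_margin),
            class = "controller_params")
}

#' One controller evaluation
#'
#' @param s_l,s_r,s_c Smoothed left, right and centre detector outputs.
#' @param p A [controller_params()].
#' @return Named numeric vector with `dx` (cm), `dz` (cm) and `dv` (cm/s):
#'   the pose changes for one control step.
#' @export
controller_step <- function(s_l, s_r, s_c, p = controller_params()) {
  # near-ties count as ties (see the trial runner): FP noise must not pick
  # a direction in a symmetric world
  sgn <- if (abs(s_l - s_r) <= 1e-9) 0 else sign(s_l - s_r)
  c(dx = sgn * (max(s_l, s_r) - p$t_x) / p$div_x,
    dz = (s_c - p$t_z) / p$div_z,
    dv = -(s_l + s_r - p$t_v) / p$div_v)
}

#' Run one closed-loop corridor trial
#'
#' Steps the full system at the neural resolution (render the corridor, step
#' the three subregion arrays, advance the along-corridor position by
#' `v * dt`) and applies the controller every `control_dt`. The model is
#' fully deterministic.
#'
#' @param world A [corridor_world()].
#' @param system An [build_full_system()] result.
#' @param controller A [controller_params()].
#' @param duration Trial length in seconds (default 5).
#' @param start Starting [bee_pose()] (default: centre, 6 cm height,
#'   40 cm/s).
#' @param warmup Open-loop warm-up in seconds before the controller engages
#'   (default 1). The detector states need several smoothing time constants
#'   to charge from zero; engaging the controller against an uncharged
#'   detector (S = 0) commands a large spurious lateral lunge whose sign is
#'   set by numerical noise. During warm-up the bee coasts straight at its
#'   starting speed. Reported trial time starts at the end of warm-up.
#' @param dt Neural step in ms (default 0.1).
#' @return A `bee_trajectory`: a data frame with one row per control step
#'   (plus the initial state) and columns `t` (s), `x`, `z`, `y` (cm), `v`
#'   (cm/s), `S_L`, `S_R`, `S_C`.
#' @export
run_trial <- function(world, system, controller = controller_params(),
                      duration = 5, start = bee_pose(), warmup = 1,
                      dt = 0.1) {
  stopifnot(inherits(world, "corridor_world"),
            inherits(system, "avdu_full_system"),
            inherits(controller, "controller_params"),
            inherits(start, "bee_pose"))
  if (duration <= 0) stop("`duration` must be positive (s)")
  csteps <- controller$control_dt / dt
  if (abs(csteps - round(csteps)) > 1e-9)
    stop("`control_dt` must be a multiple of the simulation step `dt`")
  subs <- lapply(system$subregions, function(s)
    list(dirs = s$dirs, from0 = as.integer(s$from) - 1L,
         to0 = as.integer(s$to) - 1L))
  ctrl <- list(t_x = controller$t_x, t_z = controller$t_z,
               t_v = controller$t_v, div_x = controller$div_x,
               div_z = controller$div_z, div_v = controller$div_v,
               control_steps = as.integer(round(csteps)),
               clamp_margin = controller$clamp_margin)
  m <- cpp_run_trial(world_for_cpp(world), params_for_cpp(system$params, dt),
                     unname(subs), ctrl, duration, warmup,
                     c(start$x, start$y, start$z, start$v), dt)
  traj <- as.data.frame(m)
  names(traj) <- c("t", "x", "z", "y", "v", "S_L", "S_R", "S_C")
  attr(traj, "world") <- world
  attr(traj, "controller") <- controller
  class(traj) <- c("bee_trajectory", "data.frame")
  traj
}

#' Mean lateral offset over the final window of a trial
#'
#' @param traj A [run_trial()] trajectory.
#' @param window Averaging window in seconds counted from the end (default
#'   2).
#' @return Mean of `x` over the final window, in cm (positive = toward the
#'   right wall).
#' @export
final_offset <- function(traj, window = 2) {
  tmax <- max(traj$t)
  mean(traj$x[traj$t > tmax - window])
}

#' Visual-odometry metric of a trial
#'
#' The summed lateral detector output per unit distance travelled:
#' `D_E = sum_t (S_L(t) + S_R(t)) / D`, with the sum taken over control
#' steps and `D` the along-corridor path length in cm. A detector suitable
#' for odometry yields the same `D_E` whatever the wall pattern.
#'
#' @param traj A [run_trial()] trajectory.
#' @return The scalar `D_E` (detector-output units per cm).
#' @export
odometry_metric <- function(traj) {
  d <- traj$y[nrow(traj)] - traj$y[1]
  if (!is.finite(d) || d <= 0)
    stop("total distance travelled is zero; odometry metric undefined")
  sum(traj$S_L[-1] + traj$S_R[-1]) / d
}

#' @export
print.bee_trajectory <- function(x, ...) {
  cat(sprintf("Corridor trial: %.2f s, %d control steps\n", max(x$t),
              nrow(x) - 1L))
  cat(sprintf("  final pose: x = %.2f cm, z = %.2f cm, y = %.1f cm, v = %.1f cm/s\n",
              x$x[nrow(x)], x$z[nrow(x)], x$y[nrow(x)], x$v[nrow(x)]))
  cat(sprintf("  mean lateral offset over final 2 s: %.2f cm\n",
              final_offset(x)))
  invisible(x)
}

#' @export
plot.bee_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  w <- attr(x, "world")
  graphics::plot(x$y, x$x, type = "l", xlab = "along corridor y (cm)",
                 ylab = "lateral x (cm)",
                 ylim = if (!is.null(w)) c(-w$width / 2, w$width / 2), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$t, x$S_L + x$S_R, type = "l", xlab = "t (s)",
                 ylab = expression(S[L] + S[R]), ...)
  invisible(x)
}
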