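#' Virtual Cartesian robot state
#'
#' The robot carries the micro cameras and laser on an XY carriage plus a Z
#' head; positions are integer motor steps. Axis orientation: +x steps move
#' the head right (world +x), +y steps move it up (world +y).
#'
#' @param carriage XY carriage position, steps.
#' @param head_z head height, steps.
#' @param laser_on logical.
#' @param limits symmetric travel limit per axis, steps.
#' @return An object of class `robot_state`.
#' @export
robot_state <- function(carriage = c(0, 0), head_z = 0, laser_on = FALSE,
                        limits = 30000) {
  if (any(abs(carriage) > limits) || abs(head_z) > limits)
    stop("travel-limit: position outside axis travel limits")
  structure(list(carriage = as.numeric(carriage), head_z = head_z,
                 laser_on = isTRUE(laser_on), limits = limits),
            class = "robot_state")
}

#' @export
print.robot_state <- function(x, ...) {
  cat(sprintf("<robot_state: carriage (%g, %g) stp, z %g stp, laser %s>\n",
              x$carriage[1], x$carriage[2], x$head_z,
              if (x$laser_on) "on" else "off"))
  invisible(x)
}

#' Pixel-to-step conversion model
#'
#' Linear models relating pixel errors in the macro or micro image to motor
#' steps. The configured constants are steps per pixel, so multiplying a
#' pixel error by the ratio yields the step command directly. By default
#' they are derived from the rig geometry: with a step pitch of
#' `mm_per_step` and camera pitches in micrometres per pixel,
#' `steps_per_pixel = scale / (1000 * mm_per_step)`.
#'
#' @param macro_steps_per_pixel steps per macro pixel.
#' @param micro_steps_per_pixel steps per micro pixel.
#' @param v_max maximum axis speed, steps/s.
#' @param a_max maximum axis acceleration, steps/s^2.
#' @param mm_per_step linear step pitch, mm (default 1.09 um/step, the pitch
#'   under which displacement modules convert to micrometres 1:1.09).
#' @param macro_cam,micro_cam cameras to derive defaults from.
#' @return An object of class `step_model`.
#' @export
step_model <- function(macro_steps_per_pixel = NULL,
                       micro_steps_per_pixel = NULL,
                       v_max = 8000, a_max = 25000,
                       mm_per_step = 0.00109,
                       macro_cam = macro_camera(),
                       micro_cam = micro_camera()) {
  if (is.null(macro_steps_per_pixel))
    macro_steps_per_pixel <- macro_cam$scale / (1000 * mm_per_step)
  if (is.null(micro_steps_per_pixel))
    micro_steps_per_pixel <- micro_cam$scale / (1000 * mm_per_step)
  vals <- c(macro_steps_per_pixel, micro_steps_per_pixel, v_max, a_max,
            mm_per_step)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid-parameter: step model constants must be positive")
  structure(list(macro_steps_per_pixel = macro_steps_per_pixel,
                 micro_steps_per_pixel = micro_steps_per_pixel,
                 v_max = v_max, a_max = a_max, mm_per_step = mm_per_step),
            class = "step_model")
}

#' Field-of-view geometry for the parallax error model
#'
#' @param alpha half field of view, radians (default 20.7 degrees, i.e.
#'   41.41/2 degrees).
#' @param agar_dz nominal agar height variability, mm.
#' @return An object of class `geometry_model`.
#' @export
geometry_model <- function(alpha = 20.7 * pi / 180, agar_dz = 1) {
  if (alpha <= 0 || alpha >= pi / 2)
    stop("invalid-parameter: 'alpha' must be in (0, pi/2)")
  structure(list(alpha = alpha, agar_dz = agar_dz), class = "geometry_model")
}

# round half away from zero (commercial rounding), vectorized
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a pixel error to a motor-step command
#'
#' The observed pixel error is multiplied by the steps-per-pixel ratio of
#' the chosen resolution and rounded half away from zero.
#'
#' @param error pixel error, length-2 `c(ex, ey)` (or n x 2 matrix).
#' @param model a [step_model()].
#' @param which `"macro"` or `"micro"` ratio.
#' @return Integer step command of the same shape as `error`.
#' @examples
#' m <- step_model(micro_steps_per_pixel = 1.14)
#' pixels_to_steps(c(100, 0), m, "micro")  # 114, 0
#' @export
pixels_to_steps <- function(error, model, which = c("macro", "micro")) {
  which <- match.arg(which)
  spp <- if (which == "macro") model$macro_steps_per_pixel else
    model$micro_steps_per_pixel
  round_half_away(error * spp)
}

#' Parallax positioning error from agar height variation
#'
#' A height change `dz` of the imaged surface shifts the apparent XY
#' position by `dz * tan(alpha)`, with `alpha` the half field of view.
#'
#' @param dz height change, mm (may be negative).
#' @param geometry a [geometry_model()].
#' @return XY error in mm, same sign as `dz`.
#' @examples
#' parallax_error(1, geometry_model())  # ~0.378 mm at alpha = 20.7 deg
#' @export
parallax_error <- function(dz, geometry = geometry_model()) {
  dz * tan(geometry$alpha)
}

#' Project the head laser into the macro image
#'
#' The laser marks the head (micro camera) position on the macro image.
#' This is the rig's ground-truth projection: carriage steps map affinely
#' to world mm (`carriage * mm_per_step`) and then through the macro camera
#' into pixels. Returns `NULL` when the laser is off.
#'
#' @param state a [robot_state()].
#' @param model a [step_model()] (supplies `mm_per_step`).
#' @param camera the macro [camera_model()].
#' @param scene optional scene (unused by the projection; accepted so the
#'   call mirrors the rendering API).
#' @return 0-based pixel coordinate `c(x, y)`, or `NULL` if the laser is
#'   off.
#' @export
project_laser <- function(state, model, camera = macro_camera(),
                          scene = NULL) {
  if (!state$laser_on) return(NULL)
  world <- state$carriage * model$mm_per_step
  unname(world_to_pixel(camera, world))
}

# head world position implied by the carriage, mm
carriage_world <- function(state, model) state$carriage * model$mm_per_step

#' Move the carriage by a step command
#'
#' Positions update exactly; the motion duration comes from a trapezoidal
#' velocity profile per axis under `v_max` / `a_max` (triangular when the
#' move is too short to reach `v_max`), the slower axis dominating.
#'
#' @param state a [robot_state()].
#' @param dsteps step increment `c(sx, sy)`.
#' @param model a [step_model()] (supplies the velocity limits).
#' @return A list with `state` (updated [robot_state()]) and `duration`
#'   (seconds).
#' @export
move_carriage <- function(state, dsteps, model = step_model()) {
  target <- state$carriage + dsteps
  if (any(abs(target) > state$limits))
    stop("travel-limit: commanded move exceeds axis travel limits")
  state$carriage <- target
  list(state = state,
       duration = max(vapply(abs(dsteps), axis_move_time, 0,
                             v = model$v_max, a = model$a_max)))
}

axis_move_time <- function(d, v, a) {
  if (d == 0) return(0)
  if (d <= v^2 / a) 2 * sqrt(d / a) else d / v + v / a
}
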