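#' Controller state machine
#'
#' The controller sequences: constant whole-plate software tracking
#' (`MACROTRACK`), worm selection (`SELECT`), laser-guided goal acquisition
#' (`GOAL_ACQUISITION`), micro-level centroid servoing (`MICROTRACK`),
#' autofocus (`FOCUS`) and the 30 s high-resolution capture (`CAPTURE`),
#' after which the loop restarts with the next untested worm. Software
#' macrotracking keeps running throughout; the states describe the
#' mechanical-tracking task.
#'
#' @format `machine_states` is the character vector of state names;
#'   `machine_transitions` is a two-column matrix of the legal state-graph
#'   edges.
#' @export
machine_states <- c("MACROTRACK", "SELECT", "GOAL_ACQUISITION",
                    "MICROTRACK", "FOCUS", "CAPTURE")

#' @rdname machine_states
#' @export
machine_transitions <- rbind(
  c("MACROTRACK", "SELECT"),            # a worm is available
  c("SELECT", "GOAL_ACQUISITION"),      # worm chosen, laser on
  c("SELECT", "MACROTRACK"),            # nothing selectable
  c("GOAL_ACQUISITION", "MICROTRACK"),  # error < threshold
  c("GOAL_ACQUISITION", "SELECT"),      # acquisition failed, skip
  c("MICROTRACK", "FOCUS"),             # worm centred
  c("MICROTRACK", "GOAL_ACQUISITION"),  # target lost
  c("FOCUS", "CAPTURE"),                # in focus
  c("FOCUS", "SELECT"),                 # focus failed, skip
  c("CAPTURE", "MACROTRACK"),           # sequence complete
  c("CAPTURE", "GOAL_ACQUISITION")      # target lost mid-capture
)

#' Validate a state trace against the machine graph
#'
#' @param states character vector of visited states in order.
#' @return `TRUE` invisibly; errors on an illegal transition.
#' @export
validate_state_trace <- function(states) {
  if (!all(states %in% machine_states))
    stop("invalid-parameter: unknown state in trace")
  if (length(states) > 1) {
    edges <- paste(machine_transitions[, 1], machine_transitions[, 2])
    seen <- paste(states[-length(states)], states[-1])
    seen <- seen[states[-length(states)] != states[-1]]
    bad <- setdiff(seen, edges)
    if (length(bad))
      stop("invalid state transition: ", bad[1])
  }
  invisible(TRUE)
}

#' Capture schedule
#'
#' @param macro_rate whole-plate frame rate, frames/s (default 1).
#' @param micro_rate high-resolution frame rate, frames/s (default 2).
#' @param micro_duration capture length per worm, s (default 30, i.e. 60
#'   frames at the default rate).
#' @return An object of class `capture_schedule`.
#' @export
capture_schedule <- function(macro_rate = 1, micro_rate = 2,
                             micro_duration = 30) {
  if (macro_rate <= 0 || micro_rate <= 0 || micro_duration <= 0)
    stop("invalid-parameter: rates and duration must be > 0")
  structure(list(macro_rate = macro_rate, micro_rate = micro_rate,
                 micro_duration = micro_duration,
                 n_frames = round(micro_rate * micro_duration)),
            class = "capture_schedule")
}

#' Select the next worm to capture
#'
#' The lowest-id worm that is currently tracked, has never been censored
#' and is not yet in the tested set; `NULL` when every candidate has been
#' tested.
#'
#' @param table a [new_track_table()].
#' @return A worm id, or `NULL`.
#' @export
select_next_worm <- function(table) {
  ids <- setdiff(table$last$worm_id,
                 union(table$censored_ids, table$tested))
  if (!length(ids)) NULL else min(ids)
}

#' One goal-acquisition iteration
#'
#' The pixel error between the selected worm and the laser spot in the
#' macro image is multiplied by the macro steps-per-pixel ratio to give the
#' carriage command (the y pixel axis points down while the +y motor axis
#' moves the head up, hence the sign flip on y). The loop switches to
#' microtracking once the Euclidean error drops below `tol` (15 pixels).
#'
#' @param laser_pxl laser spot pixel coordinate `c(x, y)`.
#' @param worm_pxl worm centroid pixel coordinate `c(x, y)`.
#' @param model a [step_model()].
#' @param tol switch-to-microtracking threshold, pixels.
#' @return A list with `command` (steps `c(sx, sy)`), `error` (Euclidean
#'   pixel error) and `done` (error below `tol`).
#' @export
goal_acquisition_step <- function(laser_pxl, worm_pxl, model, tol = 15) {
  if (is.null(laser_pxl))
    stop("acquisition-error: laser not detected in macro frame")
  e <- as.numeric(worm_pxl) - as.numeric(laser_pxl)
  err <- sqrt(sum(e^2))
  done <- err < tol
  command <- if (done) c(0, 0) else
    unname(pixels_to_steps(c(e[1], -e[2]), model, "macro"))
  list(command = command, error = err, done = done)
}

#' Detect the laser spot in a macro frame
#'
#' Centroid of saturated pixels (the laser is rendered saturated; the
#' dimmer secondary beamsplitter reflection stays below the threshold).
#'
#' @param frame a macro [rig_frame()].
#' @param threshold saturation threshold, grey levels.
#' @return 0-based pixel coordinate `c(x, y)`, or `NULL` when no saturated
#'   spot is present.
#' @export
detect_laser_spot <- function(frame, threshold = 250) {
  idx <- which(frame$pixels >= threshold, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

# centroid of the worm silhouette in a micro frame (0-based pixels);
# NULL when nothing dark enough is visible. `reference` is the expected
# background level (the active-vision loop drives the image there); when
# unknown, the frame median stands in.
micro_centroid <- function(frame, contrast = 60, reference = NULL) {
  bg <- if (is.null(reference)) stats::median(frame$pixels) else reference
  thr <- bg - contrast / 2
  idx <- which(frame$pixels < thr, arr.ind = TRUE)
  if (nrow(idx) < 10) return(NULL)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

#' One micro-level centroid servo step
#'
#' With the laser off, the worm centroid is segmented in the micro frame
#' and the command that carries it back to the image centre is computed
#' through the micro steps-per-pixel ratio.
#'
#' @param frame a micro [rig_frame()].
#' @param model a [step_model()].
#' @param contrast expected worm darkness below background, grey levels.
#' @return A list with `command` (steps, in the image-shift convention:
#'   the shift that carries the centroid back to the image centre),
#'   `carriage_delta` (the equal-magnitude, opposite-sign physical carriage
#'   move implementing it), `error_px` (Euclidean pixel offset of the
#'   centroid from the image centre) and `centroid`.
#' @export
microtrack_step <- function(frame, model, contrast = 60, reference = NULL) {
  cen <- micro_centroid(frame, contrast, reference)
  if (is.null(cen))
    stop("lost-target: no worm found in micro frame")
  ctr <- sensor_centre_px(frame$camera)
  e <- ctr - cen
  command <- unname(pixels_to_steps(c(e[1], -e[2]), model, "micro"))
  list(command = command, carriage_delta = -command,
       error_px = unname(sqrt(sum(e^2))), centroid = cen)
}

#' Autofocus over a set of head heights
#'
#' Captures a frame at each candidate height and returns the height
#' maximizing the sharpness score (mean squared intensity gradient).
#'
#' @param z_candidates head heights to test, steps (>= 2 after
#'   deduplication is not required; a single repeated candidate returns
#'   itself).
#' @param capture a function `z -> rig_frame` (or bare pixel matrix).
#' @return The best `z`; errors with `focus-failure` when every candidate
#'   frame is uniform.
#' @export
autofocus <- function(z_candidates, capture) {
  if (length(z_candidates) < 2)
    stop("invalid-parameter: need at least 2 focus candidates")
  score <- vapply(z_candidates, function(z) {
    f <- capture(z)
    px <- if (inherits(f, "rig_frame")) f$pixels else f
    sharpness_score(px)
  }, 0)
  if (all(score <= 0))
    stop("focus-failure: all candidate frames are uniform")
  z_candidates[which.max(score)]
}

sharpness_score <- function(px) {
  gx <- px[, -1, drop = FALSE] - px[, -ncol(px), drop = FALSE]
  gy <- px[-1, , drop = FALSE] - px[-nrow(px), , drop = FALSE]
  mean(gx^2) + mean(gy^2)
}

#' Controller configuration
#'
#' Collects the cameras, step model, capture schedule, segmentation
#' parameters and controller thresholds used by [run_session()].
#'
#' @param macro_cam,micro_cam [camera_model()]s.
#' @param model a [step_model()] (defaults derived from the cameras).
#' @param schedule a [capture_schedule()].
#' @param seg_params [segmentation_params()] (defaults derived from
#'   `macro_cam`).
#' @param backlight uniform backlight reference level, grey.
#' @param contrast worm rendering contrast, grey levels.
#' @param acquire_tol goal-acquisition switch threshold, pixels.
#' @param acquire_max_iter acquisition iterations before the worm is
#'   skipped.
#' @param precenter_ticks micro servo ticks to centre the worm before
#'   focusing.
#' @param z_candidates autofocus candidate heights, steps.
#' @param use_sigmoid_circle illuminate the worm-goal with the
#'   high-intensity sigmoid circle during micro capture.
#' @param double_spot render the secondary laser reflection.
#' @param keep_frames retain captured micro frames in the session object
#'   (memory-hungry; capture counts are recorded regardless).
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(macro_cam = macro_camera(),
                              micro_cam = micro_camera(),
                              model = NULL, schedule = capture_schedule(),
                              seg_params = NULL, backlight = 180,
                              contrast = 60, acquire_tol = 15,
                              acquire_max_iter = 5, precenter_ticks = 5,
                              z_candidates = seq(-40, 40, by = 20),
                              use_sigmoid_circle = TRUE,
                              double_spot = FALSE, keep_frames = FALSE) {
  if (is.null(model))
    model <- step_model(macro_cam = macro_cam, micro_cam = micro_cam)
  if (is.null(seg_params))
    seg_params <- default_segmentation_params(macro_cam,
                                              frame_interval = 1 / schedule$macro_rate)
  structure(list(macro_cam = macro_cam, micro_cam = micro_cam,
                 model = model, schedule = schedule,
                 seg_params = seg_params, backlight = backlight,
                 contrast = contrast, acquire_tol = acquire_tol,
                 acquire_max_iter = acquire_max_iter,
                 precenter_ticks = precenter_ticks,
                 z_candidates = z_candidates,
                 use_sigmoid_circle = use_sigmoid_circle,
                 double_spot = double_spot, keep_frames = keep_frames),
            class = "controller_config")
}

#' Run a full monitoring session on a simulated plate
#'
#' Drives the state machine against the scene: macro frames are processed
#' at the macro rate throughout; worms are selected lowest-id first,
#' acquired with the laser, centred at micro resolution, focused, and
#' captured for `micro_duration` seconds at the micro rate (60 frames at
#' defaults). Control actions (the per-instant carriage corrections, in
#' steps) are logged at the micro tick rate; their per-instant magnitudes
#' are the displacement modules of the captured worm.
#'
#' @param scene a [simulate_trajectories()] scene. Its `dt` must divide
#'   the micro tick interval.
#' @param config a [controller_config()].
#' @return An object of class `tracking_session`: `log` (data frame
#'   `worm_id, k, t, dx_steps, dy_steps, state`), `trace` (state trace),
#'   `table` (final [new_track_table()]), `captures` (per-worm capture
#'   metadata and optionally frames), `skipped` (worm ids abandoned after
#'   repeated acquisition failure).
#' @export
run_session <- function(scene, config = controller_config()) {
  sch <- config$schedule
  tick <- 1 / sch$micro_rate
  macro_every <- max(1L, round((1 / sch$macro_rate) / tick))
  if (abs(scene$dt - tick) > 1e-9 && abs(round(tick / scene$dt) * scene$dt - tick) > 1e-9)
    stop("invalid-parameter: scene dt must divide the micro tick interval")

  model <- config$model
  robot <- robot_state(limits = max(3e4, ceiling(scene$plate_radius /
                                                   model$mm_per_step) + 1000))
  table <- new_track_table()
  state <- "MACROTRACK"
  trace <- list()
  log <- list()
  captures <- list()
  skipped <- integer()
  sel <- NULL
  acq_iter <- 0L
  pre_ticks <- 0L
  cap_count <- 0L
  cap_k <- 0L
  cap_log_start <- 0L
  cap_frames <- NULL
  goal_px <- NULL
  n_ticks <- floor(scene$duration / tick + 1e-9)

  push_trace <- function(t, s, w)
    trace[[length(trace) + 1L]] <<- data.frame(t = t, state = s,
                                               worm_id = if (is.null(w)) NA_integer_ else w)
  sigmoid_bg <- NULL
  macro_backlight <- function() {
    if (config$use_sigmoid_circle && !is.null(goal_px) &&
        state %in% c("MICROTRACK", "FOCUS", "CAPTURE")) {
      if (is.null(sigmoid_bg)) {
        r <- 2 * 1000 / config$macro_cam$scale  # ~ two body lengths
        sigmoid_bg <<- sigmoid_circle_pattern(
          sigmoid_circle_spec(goal_px, radius = r, low = config$backlight,
                              high = 245, slope = r / 4),
          config$macro_cam$image_size)
      }
      sigmoid_bg
    } else config$backlight
  }
  micro_view <- function(t, z = NULL) {
    cam <- config$micro_cam
    cam$centre_world <- carriage_world(robot, model)
    render_micro_frame(scene, t, cam$centre_world, z = z, camera = cam,
                       backlight = config$backlight,
                       contrast = config$contrast)
  }

  for (i in 0:n_ticks) {
    t <- i * tick
    macro_frame <- NULL
    if (i %% macro_every == 0) {
      laser_px <- if (robot$laser_on) project_laser(robot, model,
                                                    config$macro_cam) else NULL
      macro_frame <- render_macro_frame(scene, t, macro_backlight(),
                                        laser_spot = laser_px,
                                        camera = config$macro_cam,
                                        contrast = config$contrast,
                                        double_spot = config$double_spot)
      det <- classify_by_size(segment_adaptive(macro_frame, config$seg_params),
                              config$seg_params, frame_t = t)
      # the saturated laser spot corrupts segmentation in its neighbourhood
      # (fragments, dropouts): ignore detections there while the laser is on
      # and keep the occluded worm's identity alive instead
      if (!is.null(laser_px) && nrow(det)) {
        d2 <- sqrt((det$cx - laser_px[1])^2 + (det$cy - laser_px[2])^2)
        det <- det[d2 > config$seg_params$window, , drop = FALSE]
      }
      prot <- if (robot$laser_on && !is.null(sel)) sel else integer()
      table <- track_update(table, det, t, config$seg_params$max_jump,
                            protect = prot)
    }

    repeat_tick <- TRUE
    while (repeat_tick) {
      repeat_tick <- FALSE
      if (state == "MACROTRACK") {
        if (nrow(table$rows) && !is.null(select_next_worm(table))) {
          state <- "SELECT"; push_trace(t, state, NULL)
          repeat_tick <- TRUE
        }
      } else if (state == "SELECT") {
        sel <- select_next_worm(table)
        if (is.null(sel)) {
          state <- "MACROTRACK"; push_trace(t, state, NULL)
          if (length(table$last$worm_id) &&
              !length(setdiff(table$last$worm_id,
                              union(table$censored_ids, table$tested))))
            break
        } else {
          acq_iter <- 0L
          robot$laser_on <- TRUE
          state <- "GOAL_ACQUISITION"; push_trace(t, state, sel)
        }
      } else if (state == "GOAL_ACQUISITION" && !is.null(macro_frame)) {
        worm_row <- table$last[table$last$worm_id == sel, ]
        laser_obs <- detect_laser_spot(macro_frame)
        fail <- FALSE
        if (!nrow(worm_row) || sel %in% table$censored_ids) fail <- TRUE
        step <- if (!fail) tryCatch(
          goal_acquisition_step(laser_obs, c(worm_row$cx, worm_row$cy),
                                model, config$acquire_tol),
          error = function(e) NULL) else NULL
        if (is.null(step)) fail <- TRUE
        if (getOption("wormrig.debug", FALSE))
          message(sprintf("t=%.1f acq: sel=%s rows=%d laser=%s iter=%d err=%s",
                          t, sel, nrow(worm_row),
                          !is.null(laser_obs), acq_iter,
                          if (is.null(step)) "NA" else round(step$error, 1)))
        if (fail || acq_iter >= config$acquire_max_iter) {
          if (!is.null(sel)) {
            skipped <- union(skipped, sel)
            table$tested <- sort(union(table$tested, sel))
          }
          robot$laser_on <- FALSE
          state <- "SELECT"; push_trace(t, state, NULL)
        } else if (step$done) {
          goal_px <- c(worm_row$cx, worm_row$cy)
          sigmoid_bg <- NULL
          robot$laser_on <- FALSE
          pre_ticks <- 0L
          state <- "MICROTRACK"; push_trace(t, state, sel)
        } else {
          robot <- move_carriage(robot, step$command, model)$state
          acq_iter <- acq_iter + 1L
        }
      } else if (state == "MICROTRACK") {
        res <- tryCatch(microtrack_step(micro_view(t, robot$head_z), model,
                                        config$contrast,
                                        reference = config$backlight),
                        error = function(e) NULL)
        if (getOption("wormrig.debug", FALSE))
          message(sprintf("t=%.1f micro: sel=%s err=%s pre=%d", t, sel,
                          if (is.null(res)) "LOST" else round(res$error_px, 1),
                          pre_ticks))
        if (is.null(res)) {
          robot$laser_on <- TRUE
          state <- "GOAL_ACQUISITION"; push_trace(t, state, sel)
        } else {
          robot <- move_carriage(robot, res$carriage_delta, model)$state
          pre_ticks <- pre_ticks + 1L
          if (res$error_px < 20 || pre_ticks >= config$precenter_ticks) {
            state <- "FOCUS"; push_trace(t, state, sel)
          }
        }
      } else if (state == "FOCUS") {
        best <- tryCatch(
          autofocus(config$z_candidates, function(z) micro_view(t, z)),
          error = function(e) NULL)
        if (is.null(best)) {
          skipped <- union(skipped, sel)
          table$tested <- sort(union(table$tested, sel))
          state <- "SELECT"; push_trace(t, state, NULL)
        } else {
          robot$head_z <- best
          cap_count <- 0L
          cap_k <- 0L
          cap_log_start <- length(log)
          cap_frames <- if (config$keep_frames) list() else NULL
          state <- "CAPTURE"; push_trace(t, state, sel)
          repeat_tick <- TRUE
        }
      } else if (state == "CAPTURE") {
        fr <- micro_view(t, robot$head_z)
        res <- tryCatch(microtrack_step(fr, model, config$contrast,
                                        reference = config$backlight),
                        error = function(e) NULL)
        if (is.null(res)) {
          log <- log[seq_len(cap_log_start)]  # drop the partial capture
          robot$laser_on <- TRUE
          state <- "GOAL_ACQUISITION"; push_trace(t, state, sel)
        } else {
          cap_k <- cap_k + 1L
          log[[length(log) + 1L]] <- data.frame(
            worm_id = sel, k = cap_k, t = t,
            dx_steps = res$carriage_delta[1], dy_steps = res$carriage_delta[2],
            state = "CAPTURE")
          robot <- move_carriage(robot, res$carriage_delta, model)$state
          cap_count <- cap_count + 1L
          if (config$keep_frames) cap_frames[[cap_count]] <- fr
          if (cap_count >= sch$n_frames) {
            captures[[as.character(sel)]] <- list(
              worm_id = sel, n_frames = cap_count,
              t_end = t, z = robot$head_z, frames = cap_frames)
            table$tested <- sort(union(table$tested, sel))
            goal_px <- NULL
            state <- "MACROTRACK"; push_trace(t, state, NULL)
          }
        }
      }
    }
  }

  log <- if (length(log)) do.call(rbind, log) else
    data.frame(worm_id = integer(), k = integer(), t = numeric(),
               dx_steps = numeric(), dy_steps = numeric(),
               state = character())
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(t = numeric(), state = character(), worm_id = integer())
  structure(list(log = log, trace = trace, table = table,
                 captures = captures, skipped = sort(skipped),
                 schedule = sch),
            class = "tracking_session")
}

#' @export
print.tracking_session <- function(x, ...) {
  cat(sprintf("<tracking_session: %d worms captured (%d frames each), %d skipped, %d control actions>\n",
              length(x$captures), x$schedule$n_frames, length(x$skipped),
              nrow(x$log)))
  invisible(x)
}

#' Extract displacement-module series from a session
#'
#' One [displacement_modules()] series per captured worm, from the logged
#' capture-state control actions (the per-instant carriage shifts in
#' steps).
#'
#' @param session a [run_session()] result or a session-log data frame.
#' @param strain strain label to attach (single value or named by worm id).
#' @return A list of `module_series`.
#' @export
modules_from_session <- function(session, strain = NA_character_) {
  log <- if (inherits(session, "tracking_session")) session$log else session
  log <- log[log$state == "CAPTURE", , drop = FALSE]
  if (inherits(session, "tracking_session")) {
    # only completed capture sequences contribute to the metrics
    done <- as.integer(names(session$captures))
    log <- log[log$worm_id %in% done, , drop = FALSE]
  }
  out <- list()
  for (w in unique(log$worm_id)) {
    d <- log[log$worm_id == w, ]
    d <- d[order(d$k), ]
    s <- if (length(strain) > 1) strain[[as.character(w)]] else strain
    out[[length(out) + 1L]] <- displacement_modules(
      cbind(d$dx_steps, d$dy_steps), input = "deltas", worm_id = w,
      strain = s)
  }
  out
}

#' Idealized image-free session from ground truth
#'
#' Derives the control actions an ideal mechanical tracker would log for
#' each worm: ground-truth positions over a `micro_duration` window are
#' quantized to motor steps and differenced at the micro tick rate. Used
#' for statistics-scale runs where rendering every frame is unnecessary;
#' the resulting log has the same shape as [run_session()]'s.
#'
#' @param scene a [simulate_trajectories()] scene (its `dt` must equal the
#'   micro tick interval).
#' @param model a [step_model()].
#' @param schedule a [capture_schedule()].
#' @return A session-log data frame (`worm_id, k, t, dx_steps, dy_steps,
#'   state`).
#' @export
sessions_from_truth <- function(scene, model = step_model(),
                                schedule = capture_schedule()) {
  tick <- 1 / schedule$micro_rate
  if (abs(scene$dt - tick) > 1e-9)
    stop("invalid-parameter: scene dt must equal the micro tick interval")
  n <- schedule$n_frames
  if (length(scene$times) < n + 1)
    stop("invalid-parameter: scene shorter than the capture window")
  out <- lapply(scene$worms, function(w) {
    pos_steps <- round(w$positions[seq_len(n + 1), , drop = FALSE] /
                         model$mm_per_step)
    d <- apply(pos_steps, 2, diff)
    data.frame(worm_id = w$worm_id, k = seq_len(n),
               t = seq_len(n) * tick, dx_steps = d[, 1], dy_steps = d[, 2],
               state = "CAPTURE")
  })
  do.call(rbind, out)
}

#' Session-log CSV round-trip
#'
#' Columns `worm_id, k, t, dx_steps, dy_steps, state`.
#'
#' @param log a session-log data frame (or [run_session()] result).
#' @param path CSV path.
#' @export
write_session_log <- function(log, path) {
  if (inherits(log, "tracking_session")) log <- log$log
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) read.csv(path)
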