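test_that("worm selection follows the lowest-id untested policy", {
  tab <- new_track_table()
  tab$last <- data.frame(worm_id = c(3L, 7L), cx = c(0, 1), cy = c(0, 1))
  tab$tested <- c(3L, 7L)
  expect_null(select_next_worm(tab))
  tab$tested <- 3L
  expect_equal(select_next_worm(tab), 7L)
  tab$last <- data.frame(worm_id = c(2L, 5L), cx = c(0, 1), cy = c(0, 1))
  tab$tested <- integer()
  tab$censored_ids <- 2L
  expect_equal(select_next_worm(tab), 5L)
})

test_that("goal acquisition converges within the stated iteration counts", {
  cam <- desk_macro()
  truth <- step_model(macro_cam = cam, micro_cam = desk_micro())
  # closed loop against the exact projection model; returns iterations
  # needed to bring the error under 15 pxl
  iterations_needed <- function(start_offset_px, model_used, max_iter = 6) {
    worm_px <- c(255.5, 255.5) + c(0.7, -0.3)  # fixed target near centre
    start_world <- pixel_to_world(cam, worm_px + start_offset_px)
    rb <- robot_state(round(start_world / truth$mm_per_step),
                      laser_on = TRUE, limits = 1e7)
    for (it in 0:max_iter) {
      laser <- project_laser(rb, truth, cam)
      st <- goal_acquisition_step(laser, worm_px, model_used)
      if (st$done) return(it)
      rb <- move_carriage(rb, st$command, truth)$state
    }
    Inf
  }

  expect_equal(goal_acquisition_step(c(5, 5), c(5, 5), truth)$command,
               c(0, 0))
  expect_true(goal_acquisition_step(c(5, 5), c(10, 5), truth)$done)
  expect_error(goal_acquisition_step(NULL, c(0, 0), truth),
               "acquisition-error")

  set.seed(31)
  miscaled <- truth
  miscaled$macro_steps_per_pixel <- 0.8 * truth$macro_steps_per_pixel
  for (i in 1:25) {
    ang <- runif(1, 0, 2 * pi)
    # exact model: any start in the image converges in one iteration
    r_full <- runif(1, 20, 1000)
    expect_lte(iterations_needed(r_full * c(cos(ang), sin(ang)), truth), 1)
    # 20%-mis-scaled model: geometric contraction 0.2^k e0, so two
    # iterations suffice from errors up to 15 / 0.2^2 = 375 pxl
    r_mid <- runif(1, 20, 375)
    expect_lte(iterations_needed(r_mid * c(cos(ang), sin(ang)), miscaled), 2)
    # ... and three from anywhere up to 1000 pxl
    r_big <- runif(1, 375, 1000)
    expect_lte(iterations_needed(r_big * c(cos(ang), sin(ang)), miscaled), 3)
  }
})

test_that("micro servo commands recentre the observed centroid", {
  m <- step_model(micro_steps_per_pixel = 1.14,
                  macro_steps_per_pixel = 25)
  cam <- camera_model(scale = 1.09, image_size = c(201L, 301L),
                      kind = "micro")
  blob <- function(cx0, cy0) {
    px <- matrix(180, 201, 301)
    for (i in -3:3) for (j in -3:3)
      px[cy0 + 1 + i, cx0 + 1 + j] <- 100
    rig_frame(px, 0, cam)
  }
  ctr <- c(150, 100)
  centred <- microtrack_step(blob(ctr[1], ctr[2]), m)
  expect_equal(centred$command, c(0, 0))
  off <- microtrack_step(blob(ctr[1] + 100, ctr[2]), m)
  expect_equal(off$command, c(-114, 0))
  expect_equal(off$carriage_delta, c(114, 0))
  expect_equal(off$error_px, 100)

  flat <- rig_frame(matrix(180, 201, 301), 0, cam)
  expect_error(microtrack_step(flat, m), "lost-target")
})

test_that("autofocus picks the sharpest height", {
  sc <- desk_scene(strain_model("still", 0), 1, duration = 1, seed = 5)
  cam <- desk_micro(focus_z = 20)
  head <- sc$worms[[1]]$positions[1, ]
  capture <- function(z) render_micro_frame(sc, 0, head, z = z, camera = cam)
  expect_equal(autofocus(seq(-40, 80, by = 20), capture), 20)
  expect_equal(autofocus(c(35, 35), capture), 35)
  expect_error(autofocus(7, capture), "invalid-parameter")
  flat <- function(z) matrix(128, 50, 50)
  expect_error(autofocus(c(0, 10), flat), "focus-failure")
})

test_that("state traces stay on the machine graph", {
  expect_silent(validate_state_trace(c("MACROTRACK", "SELECT",
                                       "GOAL_ACQUISITION", "MICROTRACK",
                                       "FOCUS", "CAPTURE", "MACROTRACK")))
  expect_error(validate_state_trace(c("MACROTRACK", "CAPTURE")),
               "invalid state transition")
  expect_error(validate_state_trace(c("MACROTRACK", "NAP")),
               "invalid-parameter")
})

test_that("a stationary worm yields 60 frames and null control actions", {
  sc <- desk_scene(strain_model("still", 0), 1, duration = 40, seed = 2)
  ses <- run_session(sc, desk_config())
  expect_length(ses$captures, 1)
  expect_equal(ses$captures[[1]]$n_frames, 60)
  log <- ses$log[ses$log$state == "CAPTURE", ]
  expect_equal(nrow(log), 60)
  expect_true(all(abs(log$dx_steps) <= 1 & abs(log$dy_steps) <= 1))
  expect_silent(validate_state_trace(ses$trace$state))
})

test_that("an empty plate produces an empty session", {
  sc <- desk_scene(n = 0, duration = 6, seed = 2)
  ses <- run_session(sc, desk_config())
  expect_length(ses$captures, 0)
  expect_equal(nrow(ses$log), 0)
})

test_that("session control actions track ground-truth displacement", {
  sc <- desk_scene(strain_presets("wild_type"), 1, duration = 40, seed = 3)
  cfg <- desk_config()
  ses <- run_session(sc, cfg)
  expect_length(ses$captures, 1)
  log <- ses$log[ses$log$state == "CAPTURE", ]
  expect_equal(nrow(log), 60)
  k0 <- round(log$t[1] / sc$dt)
  w <- sc$worms[[1]]
  pos_steps <- w$positions[k0:(k0 + 60), ] / cfg$model$mm_per_step
  truth <- displacement_modules(pos_steps)$modules
  got <- modules_from_session(ses)[[1]]$modules
  expect_lte(max(abs(got - truth)), 1 + 1e-9)  # one step quantization
  # summed control actions ~ total ground-truth displacement
  expect_equal(sum(got), sum(truth), tolerance = 0.02)
  expect_silent(validate_state_trace(ses$trace$state))
})

test_that("idealized sessions quantize ground truth exactly", {
  sc <- simulate_trajectories(strain_presets("wild_type"), 3,
                              duration = 30, dt = 0.5, seed = 17)
  model <- step_model()
  log <- sessions_from_truth(sc, model, capture_schedule())
  expect_equal(nrow(log), 3 * 60)
  series <- modules_from_session(log, strain = "wild_type")
  expect_length(series, 3)
  for (i in 1:3) {
    pos <- sc$worms[[i]]$positions[1:61, ] / model$mm_per_step
    truth <- displacement_modules(pos)$modules
    # per-axis step rounding moves each delta by at most 1, so the module
    # moves by at most sqrt(2)
    expect_lte(max(abs(series[[i]]$modules - truth)), sqrt(2) + 1e-9)
  }
  expect_error(sessions_from_truth(sc, model,
                                   capture_schedule(micro_duration = 60)),
               "invalid-parameter")
})

test_that("session logs survive the CSV round trip", {
  sc <- simulate_trajectories(strain_presets("wild_type"), 2,
                              duration = 30, dt = 0.5, seed = 19)
  log <- sessions_from_truth(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_equal(back$dx_steps, log$dx_steps)
  expect_equal(back$worm_id, log$worm_id)
  expect_equal(back$state, log$state)
})
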