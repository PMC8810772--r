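frame_from <- function(px, t = 0) {
  cam <- camera_model(scale = 1, image_size = dim(px), kind = "macro")
  rig_frame(px, t, cam)
}

test_that("adaptive threshold segments dark objects, not flat fields", {
  p <- segmentation_params(window = 9, offset = 10, min_area = 5,
                           max_area = 500)
  flat <- frame_from(matrix(180, 60, 60))
  expect_equal(max(segment_adaptive(flat, p)), 0)

  # dark disc on a uniform background: identical to the global-threshold
  # oracle
  px <- matrix(180, 60, 60)
  for (i in 1:60) for (j in 1:60)
    if ((i - 30)^2 + (j - 30)^2 <= 16) px[i, j] <- 100
  lab <- segment_adaptive(frame_from(px), p)
  expect_equal(max(lab), 1)
  expect_equal(which(lab > 0), which(px < 140))  # global-threshold oracle

  expect_error(segment_adaptive(flat, segmentation_params(window = 99,
                                                          min_area = 5,
                                                          max_area = 10)),
               "invalid-parameter")
  expect_error(segmentation_params(window = 4), "invalid-parameter")
  expect_error(segmentation_params(min_area = 10, max_area = 5),
               "invalid-parameter")
})

test_that("adaptive threshold beats any global threshold on a ramp", {
  # background ramps 60..220 left to right; the disc is only 40 grey
  # levels below its local background, so no global cut separates it
  n <- 80
  ramp <- matrix(rep(seq(60, 220, length.out = n), each = n), n, n,
                 byrow = FALSE)
  ramp <- t(ramp)
  disc <- ramp
  for (i in 1:n) for (j in 1:n)
    if ((i - 40)^2 + (j - 20)^2 <= 9) disc[i, j] <- disc[i, j] - 40
  in_disc <- disc < ramp
  # a global threshold that covers the whole disc necessarily swallows
  # background on the dark side of the ramp
  thr_needed <- max(disc[in_disc])
  expect_gt(sum(disc <= thr_needed & !in_disc), 0)

  p <- segmentation_params(window = 11, offset = 15, min_area = 5,
                           max_area = 100)
  lab <- segment_adaptive(frame_from(disc), p)
  det <- classify_by_size(lab, p)
  expect_equal(nrow(det), 1)
  expect_equal(det$area, sum(in_disc))
})

test_that("size classification keeps only gated components", {
  p <- segmentation_params(window = 9, offset = 10, min_area = 10,
                           max_area = 600)
  lab <- matrix(0L, 100, 100)
  lab[1, 1:2] <- 1L               # area 2
  lab[10:14, 11:18] <- 2L         # area 40
  lab[30:79, 1:100] <- 3L         # area 5000
  det <- classify_by_size(lab, p)
  expect_equal(nrow(det), 1)
  expect_equal(det$area, 40)
  expect_equal(det$cx, mean(11:18) - 1)
  expect_equal(det$cy, mean(10:14) - 1)

  expect_equal(nrow(classify_by_size(matrix(0L, 10, 10), p)), 0)
})

test_that("labelling is 8-connected", {
  p <- segmentation_params(window = 5, offset = 10, min_area = 1,
                           max_area = 50)
  px <- matrix(200, 20, 20)
  px[cbind(c(5, 6, 7, 8), c(5, 6, 7, 8))] <- 50  # diagonal chain
  lab <- segment_adaptive(frame_from(px), p)
  expect_equal(max(lab), 1)
  expect_equal(nrow(classify_by_size(lab, p)), 1)
})

test_that("identity association is optimal and applies the gate", {
  prev <- data.frame(worm_id = 1L, cx = 10, cy = 10)
  a <- associate_identities(prev,
                            data.frame(cx = 12, cy = 11, area = 30),
                            max_jump = 10)
  expect_equal(a$assignment$worm_id, 1L)
  expect_false(a$assignment$is_new)
  expect_length(a$censored, 0)

  # two worms each moving a little: equals the brute-force optimum
  prev2 <- data.frame(worm_id = c(1L, 2L), cx = c(0, 100), cy = c(0, 0))
  cur2 <- data.frame(cx = c(98, 3), cy = c(2, 1), area = c(30, 30))
  a2 <- associate_identities(prev2, cur2, max_jump = 10)
  expect_equal(a2$assignment$det[a2$assignment$worm_id == 1L], 2L)
  expect_equal(a2$assignment$det[a2$assignment$worm_id == 2L], 1L)

  # a jump beyond the gate breaks the pair: censor + fresh id
  a3 <- associate_identities(prev, data.frame(cx = 50, cy = 50, area = 30),
                             max_jump = 10)
  expect_equal(a3$censored, 1L)
  expect_true(all(a3$assignment$is_new))
  expect_equal(a3$assignment$worm_id, 2L)

  # merge: one detection for two worms; the nearer keeps the id
  prev4 <- data.frame(worm_id = c(1L, 2L), cx = c(0, 8), cy = c(0, 0))
  a4 <- associate_identities(prev4, data.frame(cx = 7, cy = 0, area = 60),
                             max_jump = 10)
  expect_equal(a4$assignment$worm_id, 2L)
  expect_equal(a4$censored, 1L)
})

test_that("association equals exhaustive minimum-cost matching up to 6 objects", {
  set.seed(13)
  for (rep in 1:25) {
    np <- sample(1:6, 1); nc <- sample(1:6, 1)
    prev <- data.frame(worm_id = seq_len(np),
                       cx = runif(np, 0, 100), cy = runif(np, 0, 100))
    cur <- data.frame(cx = runif(nc, 0, 100), cy = runif(nc, 0, 100),
                      area = 30)
    a <- associate_identities(prev, cur, max_jump = 1e6)
    cost <- outer(seq_len(np), seq_len(nc), function(i, j)
      sqrt((prev$cx[i] - cur$cx[j])^2 + (prev$cy[i] - cur$cy[j])^2))
    oracle <- brute_force_assignment(cost)
    kept <- a$assignment[!a$assignment$is_new, ]
    got <- sum(cost[cbind(match(kept$worm_id, prev$worm_id), kept$det)])
    expect_equal(got, oracle$cost, tolerance = 1e-9)
  }
})

test_that("tracking recovers ground-truth identities on separated scenes", {
  cam <- desk_macro()
  params <- default_segmentation_params(cam, body_length = 0.5,
                                        body_width = 60)
  sc <- desk_scene(strain_presets("wild_type"), 4, duration = 15, seed = 21)
  # keep only scenes where worms stay far apart relative to the gate
  min_gap_px <- min(vapply(seq_along(sc$times), function(k) {
    pos <- do.call(rbind, lapply(sc$worms, function(w) w$positions[k, ]))
    min(stats::dist(pos)) * 1000 / cam$scale
  }, 0))
  expect_gt(min_gap_px, 2 * params$max_jump)

  frames <- lapply(seq(0, 15, by = 1), function(t)
    render_macro_frame(sc, t, camera = cam))
  table <- track_frames(frames, params)
  df <- table$rows[!table$rows$censored, ]
  expect_length(table$censored_ids, 0)
  expect_equal(sort(unique(df$worm_id)), 1:4)
  # every frame sees every worm exactly once
  expect_true(all(table(df$t) == 4))
  # map tracker ids to simulator ids at t = 0, then demand agreement at
  # every frame
  truth0 <- scene_positions(sc, 0)
  first <- df[df$t == 0, ]
  world0 <- pixel_to_world(cam, cbind(first$cx, first$cy))
  map <- vapply(seq_len(nrow(first)), function(i)
    truth0$worm_id[which.min((truth0$x_mm - world0[i, 1])^2 +
                               (truth0$y_mm - world0[i, 2])^2)], 0L)
  names(map) <- first$worm_id
  for (t in seq(0, 15, by = 1)) {
    cur <- df[df$t == t, ]
    truth <- scene_positions(sc, t)
    for (i in seq_len(nrow(cur))) {
      world <- pixel_to_world(cam, c(cur$cx[i], cur$cy[i]))
      nearest <- truth$worm_id[which.min((truth$x_mm - world[1])^2 +
                                           (truth$y_mm - world[2])^2)]
      expect_equal(nearest, unname(map[as.character(cur$worm_id[i])]))
    }
  }
})

test_that("track tables survive the CSV round trip", {
  sc <- desk_scene(n = 2, duration = 5, seed = 8)
  cam <- desk_macro()
  params <- default_segmentation_params(cam, body_length = 0.5,
                                        body_width = 60)
  frames <- lapply(seq(0, 5, by = 1), function(t)
    render_macro_frame(sc, t, camera = cam))
  table <- track_frames(frames, params)
  table$tested <- 1L
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_table(table, path)
  back <- read_track_table(path)
  expect_equal(back$rows$worm_id, table$rows$worm_id)
  expect_equal(back$rows$cx, table$rows$cx, tolerance = 1e-9)
  expect_equal(back$tested, table$tested)
  expect_equal(back$censored_ids, table$censored_ids)
  expect_equal(select_next_worm(back), select_next_worm(table))
})
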