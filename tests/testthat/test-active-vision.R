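# build a pattern pair: a single-dot lighting state plus the frame a
# camera looking through homography H would capture (Gaussian dot so the
# detected centroid matches the mapped position to sub-pixel accuracy)
pattern_pair <- function(dot_texel, H, frame_dim, grid_dim = c(60L, 80L)) {
  st <- matrix(0, grid_dim[1], grid_dim[2])
  st[dot_texel[2] + 1, dot_texel[1] + 1] <- 255
  centre <- wormrig:::apply_homography(H, dot_texel)
  xs <- matrix(0:(frame_dim[2] - 1), frame_dim[1], frame_dim[2], byrow = TRUE)
  ys <- matrix(0:(frame_dim[1] - 1), frame_dim[1], frame_dim[2])
  px <- 255 * exp(-((xs - centre[1])^2 + (ys - centre[2])^2) / (2 * 2^2))
  cam <- camera_model(scale = 1, image_size = frame_dim, kind = "macro")
  list(state = lighting_state(st), frame = rig_frame(px, 0, cam))
}

grid_dots <- function(n = 3, grid_dim = c(60L, 80L)) {
  xs <- round(seq(10, grid_dim[2] - 10, length.out = n))
  ys <- round(seq(10, grid_dim[1] - 10, length.out = n))
  expand.grid(x = xs, y = ys)
}

test_that("texel calibration recovers identity and known homographies", {
  frame_dim <- c(120L, 160L)
  eye <- diag(3)
  dots <- grid_dots()
  pairs <- lapply(seq_len(nrow(dots)), function(i)
    pattern_pair(c(dots$x[i], dots$y[i]), eye, frame_dim))
  map <- calibrate_texel_map(pairs)
  expect_lt(max(abs(map$H - eye)), 1e-6)

  # integer affine homography: every dot lands on an exact pixel centre,
  # so the fit must recover the generator to numerical precision
  Ha <- rbind(c(2, 0, 12), c(0, 2, 8), c(0, 0, 1))
  square_pair <- function(dot_texel) {
    st <- matrix(0, 60, 80)
    st[dot_texel[2] + 1, dot_texel[1] + 1] <- 255
    centre <- wormrig:::apply_homography(Ha, dot_texel)
    px <- matrix(0, frame_dim[1], frame_dim[2])
    px[centre[2] + 1 + (-1:1), centre[1] + 1 + (-1:1)] <- 255
    cam <- camera_model(scale = 1, image_size = frame_dim, kind = "macro")
    list(state = lighting_state(st), frame = rig_frame(px, 0, cam))
  }
  pairs_a <- lapply(seq_len(nrow(dots)), function(i)
    square_pair(c(dots$x[i], dots$y[i])))
  map_a <- calibrate_texel_map(pairs_a)
  expect_lt(max(abs(map_a$H - Ha)), 1e-3)

  # full projective map with sub-pixel dot centres: sub-0.05 pxl residual
  # and the half-texel round-trip guarantee
  H <- rbind(c(1.8, 0.04, 12), c(-0.03, 1.7, 8), c(1e-4, -5e-5, 1))
  pairs2 <- lapply(seq_len(nrow(dots)), function(i)
    pattern_pair(c(dots$x[i], dots$y[i]), H, frame_dim))
  map2 <- calibrate_texel_map(pairs2)
  expect_lt(map2$residual_px, 0.05)
  grid <- as.matrix(expand.grid(seq(0, 79, by = 8), seq(0, 59, by = 8)))
  back <- pixel_to_texel(map2, texel_to_pixel(map2, grid))
  expect_lt(max(sqrt(rowSums((back - grid)^2))), 0.5)
})

test_that("calibration needs at least four non-collinear dots", {
  frame_dim <- c(120L, 160L)
  eye <- diag(3)
  three <- lapply(list(c(10, 10), c(50, 10), c(30, 40)), pattern_pair,
                  H = eye, frame_dim = frame_dim)
  expect_error(calibrate_texel_map(three), "calibration-failure")
  collinear <- lapply(list(c(10, 10), c(20, 20), c(30, 30), c(40, 40)),
                      pattern_pair, H = eye, frame_dim = frame_dim)
  expect_error(calibrate_texel_map(collinear), "calibration-failure")
})

test_that("backlight control drives the image to the reference", {
  # identity rig on a small grid: pixel grid == texel grid,
  # camera response = texel intensity - shadow
  dim <- c(40L, 40L)
  eye_map <- structure(list(H = diag(3), Hinv = diag(3), residual_px = 0),
                       class = "texel_map")
  cam <- camera_model(scale = 1, image_size = dim, kind = "macro")
  shadow <- matrix(0, dim[1], dim[2])
  shadow[10:20, 10:20] <- 60
  observe <- function(state)
    rig_frame(pmin(pmax(unclass(state) - shadow, 0), 255), 0, cam)

  st <- lighting_state(128, dims = dim)
  ref <- 180
  # uniform frame already at reference: no change
  flat <- rig_frame(matrix(ref, dim[1], dim[2]), 0, cam)
  expect_equal(unclass(update_backlight(flat, ref, eye_map, 0.5, st)),
               unclass(st))
  # uniform frame below reference: every texel increases
  dark <- rig_frame(matrix(100, dim[1], dim[2]), 0, cam)
  up <- update_backlight(dark, ref, eye_map, 0.5, st)
  expect_true(all(unclass(up) > unclass(st)))

  # closed loop reaches the reference; the error shrinks monotonically
  errs <- numeric()
  for (i in 1:40) {
    fr <- observe(st)
    errs <- c(errs, max(abs(fr$pixels - ref)))
    st <- update_backlight(fr, ref, eye_map, 0.5, st)
  }
  fr <- observe(st)
  saturated <- unclass(st) >= 255
  expect_lt(max(abs(fr$pixels - ref)[!saturated]), 2)
  expect_true(all(diff(errs) <= 1e-9))
  expect_error(update_backlight(fr, ref, eye_map, 0, st),
               "invalid-parameter")
})

test_that("the sigmoid illumination circle has the stated profile", {
  spec <- sigmoid_circle_spec(centre = c(60, 60), radius = 30, low = 120,
                              high = 250, slope = 5)
  pat <- sigmoid_circle_pattern(spec, c(121, 121))
  # centre ~ high, far limit ~ low, exact midpoint at d = radius
  expect_equal(pat[61, 61], 250, tolerance = 1e-2)
  expect_equal(pat[1, 1], 120, tolerance = 0.5)
  expect_equal(pat[61, 91], (120 + 250) / 2, tolerance = 1e-9)  # d = 30

  # rotational symmetry: equal distance, equal intensity
  expect_equal(pat[61, 91], pat[91, 61], tolerance = 1e-12)
  expect_equal(pat[61, 31], pat[31, 61], tolerance = 1e-12)

  # radially monotone non-increasing along a ray
  ray <- pat[61, 61:121]
  expect_true(all(diff(ray) <= 1e-12))

  # spatial gradient bounded by (high - low) / (4 * slope)
  gmax <- max(abs(diff(pat)), abs(t(diff(t(pat)))))
  expect_lte(gmax, (250 - 120) / (4 * 5) * 1.0001)

  expect_error(sigmoid_circle_spec(c(0, 0), radius = -1), "invalid-parameter")
  expect_error(sigmoid_circle_spec(c(0, 0), 5, low = 200, high = 100),
               "invalid-parameter")
})

test_that("lighting fields map texels onto their owned pixels", {
  dim <- c(30L, 30L)
  eye_map <- structure(list(H = diag(3), Hinv = diag(3), residual_px = 0),
                       class = "texel_map")
  st <- lighting_state(matrix(seq(0, 255, length.out = 900), 30, 30),
                       dims = dim)
  field <- lighting_field(st, eye_map, dim)
  expect_equal(field, unclass(st), tolerance = 1e-12)
})
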