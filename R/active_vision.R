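#' Backlight display state
#'
#' The backlight is a dot display (default 800 x 480 texels) under the
#' plate; each texel holds a grey level in `[0, 255]`. Stored as a
#' `rows x cols` matrix (480 x 800 by default); texel coordinates are
#' 0-based `(x = column, y = row)` like pixel coordinates.
#'
#' @param intensities a matrix of texel levels, or a single level to fill
#'   the grid with.
#' @param dims grid size `c(rows, cols)` when `intensities` is scalar.
#' @return An object of class `lighting_state` (a matrix).
#' @export
lighting_state <- function(intensities = 128, dims = c(480L, 800L)) {
  m <- if (is.matrix(intensities)) intensities else
    matrix(intensities, dims[1], dims[2])
  m <- pmin(pmax(m, 0), 255)
  class(m) <- c("lighting_state", class(m))
  m
}

#' @export
print.lighting_state <- function(x, ...) {
  cat(sprintf("<lighting_state: %d x %d texels, levels [%.0f, %.0f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

apply_homography <- function(H, xy) {
  v <- is.null(dim(xy))
  xy <- rbind_as_matrix(xy)
  p <- cbind(xy, 1) %*% t(H)
  out <- p[, 1:2, drop = FALSE] / p[, 3]
  if (v) out[1, ] else out
}

#' Texel-to-pixel projective map
#'
#' `texel_to_pixel()` / `pixel_to_texel()` apply the fitted projective
#' transform between display texel coordinates and macro camera pixel
#' coordinates (both 0-based).
#'
#' @param map a `texel_map` from [calibrate_texel_map()].
#' @param xy texel (or pixel) coordinates, length-2 vector or n x 2 matrix.
#' @export
texel_to_pixel <- function(map, xy) apply_homography(map$H, xy)

#' @rdname texel_to_pixel
#' @export
pixel_to_texel <- function(map, xy) apply_homography(map$Hinv, xy)

# intensity-weighted centroid of the bright blob in a matrix; NULL when flat
bright_centroid <- function(m) {
  rng <- range(m)
  if (diff(rng) < 1) return(NULL)
  thr <- rng[1] + 0.5 * diff(rng)
  idx <- which(m > thr, arr.ind = TRUE)
  w <- m[idx] - thr
  c(x = sum((idx[, 2] - 1) * w) / sum(w),
    y = sum((idx[, 1] - 1) * w) / sum(w))
}

# normalized DLT homography fit, src -> dst (n x 2 each)
fit_homography <- function(src, dst) {
  norm_tf <- function(p) {
    c0 <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, c0)^2)))
    rbind(c(s, 0, -s * c0[1]), c(0, s, -s * c0[2]), c(0, 0, 1))
  }
  Ts <- norm_tf(src); Td <- norm_tf(dst)
  s <- apply_homography(Ts, src); d <- apply_homography(Td, dst)
  A <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    rbind(c(-x, -y, -1, 0, 0, 0, u * x, u * y, u),
          c(0, 0, 0, -x, -y, -1, v * x, v * y, v))
  }))
  h <- svd(A, nu = 0)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  H / H[3, 3]
}

#' Calibrate the texel-to-pixel transform
#'
#' The display shows one bright dot at a time while the macro camera
#' watches; the centroids of the dot on the display grid and in the camera
#' image form point correspondences from which the projective transform is
#' fitted by (normalized DLT) least squares. At least four non-collinear
#' correspondences are required.
#'
#' @param pattern_frames a list of `list(state = , frame = )` pairs: a
#'   [lighting_state()] with a single bright dot and the [rig_frame()]
#'   captured under it.
#' @return An object of class `texel_map`: `H` (3 x 3, texel to pixel),
#'   `Hinv`, `residual_px` (RMS reprojection residual) and the
#'   correspondences used.
#' @seealso [make_calibration_states()] to generate the dot patterns.
#' @export
calibrate_texel_map <- function(pattern_frames) {
  tx <- list(); px <- list()
  for (pf in pattern_frames) {
    ct <- bright_centroid(unclass(pf$state))
    cp <- bright_centroid(pf$frame$pixels)
    if (!is.null(ct) && !is.null(cp)) {
      tx[[length(tx) + 1L]] <- ct
      px[[length(px) + 1L]] <- cp
    }
  }
  if (length(tx) < 4)
    stop("calibration-failure: fewer than 4 dot correspondences detected")
  src <- do.call(rbind, tx); dst <- do.call(rbind, px)
  collinear <- function(p) {
    sv <- svd(sweep(p, 2, colMeans(p)))$d
    sv[2] < 1e-6 * max(sv[1], 1)
  }
  if (collinear(src) || collinear(dst))
    stop("calibration-failure: calibration dots are collinear")
  H <- fit_homography(src, dst)
  proj <- apply_homography(H, src)
  res <- sqrt(mean(rowSums((proj - dst)^2)))
  structure(list(H = H, Hinv = solve(H), residual_px = res,
                 texel_points = src, pixel_points = dst),
            class = "texel_map")
}

#' @export
print.texel_map <- function(x, ...) {
  cat(sprintf("<texel_map: %d correspondences, RMS residual %.3g pxl>\n",
              nrow(x$texel_points), x$residual_px))
  invisible(x)
}

#' Generate single-dot calibration patterns
#'
#' A grid of `n x n` lighting states, each with one bright square dot, for
#' use with [calibrate_texel_map()].
#'
#' @param n dots per side (default 5).
#' @param dims display grid `c(rows, cols)`.
#' @param dot_size dot side length, texels.
#' @param level dot grey level.
#' @return A list of [lighting_state()] objects.
#' @export
make_calibration_states <- function(n = 5, dims = c(480L, 800L),
                                    dot_size = 5, level = 255) {
  margin <- 0.1
  xs <- round(seq(margin, 1 - margin, length.out = n) * (dims[2] - 1))
  ys <- round(seq(margin, 1 - margin, length.out = n) * (dims[1] - 1))
  out <- list()
  h <- floor(dot_size / 2)
  for (y in ys) for (x in xs) {
    m <- matrix(0, dims[1], dims[2])
    rr <- pmin(pmax((y - h):(y + h) + 1L, 1L), dims[1])
    cc <- pmin(pmax((x - h):(x + h) + 1L, 1L), dims[2])
    m[rr, cc] <- level
    out[[length(out) + 1L]] <- lighting_state(m)
  }
  out
}

# owning texel (rounded inverse-mapped coordinate) for every pixel of a
# rows x cols image; returns integer matrix n_pixels x 2 (x = col, y = row,
# 0-based) aligned with column-major pixel order
pixel_owners <- function(map, image_size, grid_dims) {
  rows <- image_size[1]; cols <- image_size[2]
  px <- cbind(rep(0:(cols - 1), each = rows), rep(0:(rows - 1), cols))
  tx <- round(pixel_to_texel(map, px))
  tx[, 1] <- pmin(pmax(tx[, 1], 0), grid_dims[2] - 1)
  tx[, 2] <- pmin(pmax(tx[, 2], 0), grid_dims[1] - 1)
  tx
}

#' Closed-loop backlight update
#'
#' One proportional-control iteration of the active-vision loop: each texel
#' owns the image pixels nearest to its mapped position; texels whose
#' pixels are darker than the reference are brightened by
#' `gain * (reference - mean grey)` and brighter ones dimmed, with the
#' result clipped to `[0, 255]`. Iterating against the rig drives the macro
#' image toward a uniform reference grey level (for `0 < gain < 2` the loop
#' is a contraction under a linear camera response).
#'
#' @param frame the current macro [rig_frame()].
#' @param reference target grey level.
#' @param map the [calibrate_texel_map()] transform.
#' @param gain proportional gain (> 0; default 0.5).
#' @param state the current [lighting_state()].
#' @return The updated [lighting_state()].
#' @export
update_backlight <- function(frame, reference, map, gain = 0.5, state) {
  if (gain <= 0) stop("invalid-parameter: 'gain' must be > 0")
  owners <- pixel_owners(map, dim(frame$pixels), dim(state))
  lin <- owners[, 2] + owners[, 1] * nrow(state) + 1  # texel linear index
  grey <- as.vector(frame$pixels)
  mean_grey <- rowsum(grey, lin)
  cnt <- rowsum(rep(1, length(grey)), lin)
  tix <- as.integer(rownames(mean_grey))
  delta <- gain * (reference - mean_grey[, 1] / cnt[, 1])
  new <- unclass(state)
  new[tix] <- new[tix] + delta
  lighting_state(pmin(pmax(new, 0), 255))
}

#' Sigmoid high-intensity illumination circle
#'
#' The intensity field used during micro capture: a bright circle centred
#' on the worm-goal position whose edge falls off smoothly, following a
#' logistic sigmoid of the distance to the centre:
#' `I(d) = low + (high - low) * logistic((radius - d) / slope)`.
#' The field is radially symmetric, monotone non-increasing in `d`, equals
#' `(low + high)/2` exactly at `d = radius`, and its spatial gradient never
#' exceeds `(high - low) / (4 * slope)` per pixel, keeping illumination
#' gradients small for segmentation.
#'
#' @param centre 0-based pixel coordinate `c(x, y)` of the circle centre.
#' @param radius circle radius, pixels (> 0).
#' @param low,high outside / inside grey levels (`low <= high`).
#' @param slope transition width, pixels (> 0).
#' @return An object of class `sigmoid_circle_spec`.
#' @export
sigmoid_circle_spec <- function(centre, radius, low = 120, high = 250,
                                slope = 10) {
  if (radius <= 0 || slope <= 0 || low > high)
    stop("invalid-parameter: need radius > 0, slope > 0, low <= high")
  structure(list(centre = as.numeric(centre), radius = radius,
                 low = low, high = high, slope = slope),
            class = "sigmoid_circle_spec")
}

#' @rdname sigmoid_circle_spec
#' @param spec a `sigmoid_circle_spec`.
#' @param grid_shape output size `c(rows, cols)`.
#' @return `sigmoid_circle_pattern()` returns a `rows x cols` intensity
#'   matrix.
#' @export
sigmoid_circle_pattern <- function(spec, grid_shape) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  dx <- matrix(0:(cols - 1), rows, cols, byrow = TRUE) - spec$centre[1]
  dy <- matrix(0:(rows - 1), rows, cols) - spec$centre[2]
  d <- sqrt(dx^2 + dy^2)
  spec$low + (spec$high - spec$low) * stats::plogis((spec$radius - d) / spec$slope)
}

#' Backlight field seen by the camera
#'
#' The backlight level behind each camera pixel: every pixel takes the
#' intensity of its owning texel through the texel map. Used to turn a
#' [lighting_state()] into the `backlight` argument of
#' [render_macro_frame()].
#'
#' @param state a [lighting_state()].
#' @param map a [calibrate_texel_map()] transform.
#' @param image_size output `c(rows, cols)`.
#' @return A `rows x cols` matrix of grey levels.
#' @export
lighting_field <- function(state, map, image_size) {
  owners <- pixel_owners(map, image_size, dim(state))
  lin <- owners[, 2] + owners[, 1] * nrow(state) + 1
  matrix(unclass(state)[lin], image_size[1], image_size[2])
}
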