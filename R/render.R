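#' Image frames
#'
#' A frame is an 8-bit-range grey-level image (values in `[0, 255]`, stored
#' as a numeric `rows x cols` matrix) together with its capture time and the
#' camera that produced it.
#'
#' @param pixels numeric matrix of grey levels in `[0, 255]`.
#' @param t capture time, seconds.
#' @param camera the [camera_model()] that produced the frame.
#' @return An object of class `rig_frame`.
#' @export
rig_frame <- function(pixels, t, camera) {
  stopifnot(is.matrix(pixels))
  if (!all(dim(pixels) == camera$image_size))
    stop("invalid-parameter: pixel dimensions do not match camera image_size")
  structure(list(pixels = pixels, t = t, camera = camera,
                 kind = camera$kind), class = "rig_frame")
}

#' @export
print.rig_frame <- function(x, ...) {
  cat(sprintf("<rig_frame: %s %d x %d at t = %.2f s, grey [%",
              x$kind, nrow(x$pixels), ncol(x$pixels), x$t),
      sprintf(".0f, %.0f]>\n", min(x$pixels), max(x$pixels)), sep = "")
  invisible(x)
}

# Rasterize one worm body into `pixels` (modified copy returned).
# The body is a thick S-curved polyline: in the body frame (u along the
# heading, v across), the midline is v = A * sin(2*pi*u/L) for |u| <= L/2
# with half-round caps. The S-curve is point-symmetric about the centre, so
# the silhouette centroid coincides with the trajectory position.
draw_worm <- function(pixels, camera, centre_world, heading,
                      body_length, body_width, contrast, curve_frac = 0.08) {
  mm_per_px <- camera$scale / 1000
  L <- body_length
  halfw <- max(body_width / 2000, 0.5 * mm_per_px)  # mm; at least half a pixel
  A <- curve_frac * L
  # heading-aware bounding box (the body is long and narrow)
  ch0 <- abs(cos(heading)); sh0 <- abs(sin(heading))
  ext_x <- (ch0 * L / 2 + sh0 * A + halfw) / mm_per_px + 1
  ext_y <- (sh0 * L / 2 + ch0 * A + halfw) / mm_per_px + 1
  cpx <- world_to_pixel(camera, centre_world)
  x0 <- max(0L, floor(cpx[1] - ext_x)); x1 <- min(ncol(pixels) - 1L, ceiling(cpx[1] + ext_x))
  y0 <- max(0L, floor(cpx[2] - ext_y)); y1 <- min(nrow(pixels) - 1L, ceiling(cpx[2] + ext_y))
  if (x0 > x1 || y0 > y1) return(pixels)
  xs <- x0:x1; ys <- y0:y1
  # world offsets of the pixel grid from the worm centre
  wx <- camera$centre_world[1] +
    (xs - (camera$image_size[2] - 1) / 2) * mm_per_px - centre_world[1]
  wy <- camera$centre_world[2] -
    (ys - (camera$image_size[1] - 1) / 2) * mm_per_px - centre_world[2]
  gx <- matrix(wx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  gy <- matrix(wy, nrow = length(ys), ncol = length(xs))
  ch <- cos(heading); sh <- sin(heading)
  u <- ch * gx + sh * gy
  v <- -sh * gx + ch * gy
  uc <- pmax(pmin(u, L / 2), -L / 2)
  vm <- A * sin(2 * pi * uc / L)
  # shallow-curve distance approximation; the |v - vm| measurement is
  # vertical in the body frame, so the band is widened by the local slope
  # factor to keep the true perpendicular thickness (and hence raster
  # connectivity) at width w
  slope <- A * (2 * pi / L) * cos(2 * pi * uc / L)
  d <- sqrt((u - uc)^2 + (v - vm)^2)
  inside <- d <= halfw * sqrt(1 + slope^2)
  if (any(inside)) {
    sub <- pixels[ys + 1L, xs + 1L, drop = FALSE]
    sub[inside] <- pmax(sub[inside] - contrast, 0)
    pixels[ys + 1L, xs + 1L] <- sub
  }
  pixels
}

# paint a filled disc (0-based pixel centre) with absolute grey `value`
draw_disc <- function(pixels, centre_px, radius, value) {
  x0 <- max(0L, floor(centre_px[1] - radius)); x1 <- min(ncol(pixels) - 1L, ceiling(centre_px[1] + radius))
  y0 <- max(0L, floor(centre_px[2] - radius)); y1 <- min(nrow(pixels) - 1L, ceiling(centre_px[2] + radius))
  if (x0 > x1 || y0 > y1) return(pixels)
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - centre_px[1], nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - centre_px[2], nrow = length(ys), ncol = length(xs))
  inside <- dx^2 + dy^2 <= radius^2
  sub <- pixels[ys + 1L, xs + 1L, drop = FALSE]
  sub[inside] <- value
  pixels[ys + 1L, xs + 1L] <- sub
  pixels
}

#' Render the whole-plate macro view
#'
#' Draws every worm of the scene at time `t` as a dark silhouette on the
#' backlight field, optionally with the laser spot. Worms are rendered
#' `contrast` grey levels below the local backlight; the laser is a small
#' saturated disc, and with `double_spot = TRUE` a second, larger, dimmer
#' disc is added at the same position (the beamsplitter reflects the beam a
#' second time at a different magnification).
#'
#' @param scene a [simulate_trajectories()] scene.
#' @param t capture time in seconds (must lie within the scene).
#' @param backlight a uniform grey level, or a full `rows x cols` matrix of
#'   backlight levels (see [lighting_field()]).
#' @param laser_spot optional 0-based pixel coordinate `c(x, y)` of the
#'   laser, or `NULL` for laser off.
#' @param camera the macro [camera_model()] (default [macro_camera()]).
#' @param contrast worm darkness below the backlight, grey levels.
#' @param double_spot render the secondary beamsplitter reflection.
#' @param laser_radius radius of the saturated spot, pixels.
#' @return A [rig_frame()].
#' @export
render_macro_frame <- function(scene, t, backlight = 180, laser_spot = NULL,
                               camera = macro_camera(), contrast = 60,
                               double_spot = FALSE, laser_radius = 2) {
  k <- scene_time_index(scene, t)
  pixels <- if (is.matrix(backlight)) {
    if (!all(dim(backlight) == camera$image_size))
      stop("invalid-parameter: backlight matrix does not match image_size")
    backlight
  } else matrix(as.numeric(backlight), camera$image_size[1], camera$image_size[2])
  for (w in scene$worms)
    pixels <- draw_worm(pixels, camera, w$positions[k, ], w$headings[k],
                        w$body_length, w$body_width, contrast)
  if (!is.null(laser_spot)) {
    if (double_spot)
      pixels <- draw_disc(pixels, laser_spot, laser_radius * 2.5,
                          min(255, mean(pixels) + 40))
    pixels <- draw_disc(pixels, laser_spot, laser_radius, 255)
  }
  rig_frame(pixels, t, camera)
}

#' Render the high-resolution micro view
#'
#' Renders a crop centred on `head_world` at micro resolution. The frame is
#' sharp when the head height `z` equals the camera's `focus_z` and is
#' otherwise blurred with a Gaussian of sigma
#' `defocus_gain * |z - focus_z|` pixels. Regions outside the plate render
#' as plain backlight.
#'
#' @inheritParams render_macro_frame
#' @param head_world world coordinate (mm) of the head / crop centre.
#' @param z head height in motor steps.
#' @param camera the micro [camera_model()]; its `centre_world` is
#'   overridden by `head_world`.
#' @return A [rig_frame()].
#' @export
render_micro_frame <- function(scene, t, head_world, z = NULL,
                               camera = micro_camera(), backlight = 180,
                               contrast = 60) {
  k <- scene_time_index(scene, min(max(t, 0), scene$duration))
  camera$centre_world <- as.numeric(head_world)
  pixels <- if (is.matrix(backlight)) backlight else
    matrix(as.numeric(backlight), camera$image_size[1], camera$image_size[2])
  # only draw worms whose body can intersect the crop
  half_extent <- max(camera$image_size) / 2 * camera$scale / 1000
  for (w in scene$worms) {
    p <- w$positions[k, ]
    if (sqrt(sum((p - head_world)^2)) <= half_extent + w$body_length)
      pixels <- draw_worm(pixels, camera, p, w$headings[k],
                          w$body_length, w$body_width, contrast)
  }
  if (!is.null(z)) {
    sigma <- camera$defocus_gain * abs(z - camera$focus_z)
    if (sigma > 0.05)
      pixels <- as.matrix(EBImage::gblur(EBImage::Image(pixels), sigma = sigma))
  }
  rig_frame(pixels, t, camera)
}

#' Read and write frames as image files
#'
#' Frames are written as 8-bit greyscale PNG or TIFF (by file extension).
#'
#' @param frame a [rig_frame()].
#' @param path output image path (`.png` or `.tif`/`.tiff`).
#' @export
write_frame <- function(frame, path) {
  img <- EBImage::Image(t(frame$pixels) / 255)
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @rdname write_frame
#' @param camera camera metadata to attach on read.
#' @param t capture time to attach on read.
#' @export
read_frame <- function(path, camera = NULL, t = 0) {
  img <- EBImage::readImage(path)
  px <- t(as.matrix(img)) * 255
  if (is.null(camera))
    camera <- camera_model(scale = 1, image_size = dim(px), kind = "macro")
  rig_frame(px, t, camera)
}
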