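#' Camera models and coordinate conventions
#'
#' All coordinate transforms used by the rig live here.
#'
#' Conventions (used consistently across the package):
#' \itemize{
#'   \item \strong{World frame}: millimetres, origin at the plate centre,
#'     x to the right, y up.
#'   \item \strong{Pixel frame}: 0-based, origin at the top-left pixel centre,
#'     x = column index (rightward), y = row index (downward).
#'   \item \strong{Motor steps}: integer counts per axis; the carriage world
#'     position is `steps * mm_per_step`, +x steps move the head right,
#'     +y steps move it up (note the y sign flip against pixel rows).
#' }
#'
#' A camera is a simple pinhole-free orthographic sampler: pixel pitch
#' `scale` micrometres per pixel, aimed at `centre_world`, which maps to the
#' centre of the sensor. The micro camera additionally carries a focus model:
#' frames rendered at head height `z` are blurred with a Gaussian of sigma
#' `defocus_gain * |z - focus_z|` pixels.
#'
#' @param scale pixel pitch, micrometres per pixel (must be > 0).
#' @param image_size sensor size as `c(rows, cols)` in pixels.
#' @param centre_world world point (mm) imaged at the sensor centre.
#' @param focus_z head height (motor steps) at which the image is sharp
#'   (micro camera only).
#' @param defocus_gain Gaussian blur sigma, in pixels per step of
#'   `|z - focus_z|`.
#' @param kind `"macro"` or `"micro"`.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- macro_camera()
#' world_to_pixel(cam, c(0, 0))  # plate centre -> sensor centre
#' @export
camera_model <- function(scale, image_size, centre_world = c(0, 0),
                         focus_z = 0, defocus_gain = 0,
                         kind = c("macro", "micro")) {
  kind <- match.arg(kind)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("invalid-parameter: 'scale' must be a single positive number")
  if (length(image_size) != 2L || any(image_size < 1))
    stop("invalid-parameter: 'image_size' must be c(rows, cols) >= 1")
  structure(list(
    scale = scale,
    image_size = as.integer(image_size),
    centre_world = as.numeric(centre_world),
    focus_z = focus_z,
    defocus_gain = defocus_gain,
    kind = kind
  ), class = "camera_model")
}

#' @rdname camera_model
#' @export
macro_camera <- function(scale = 27.31, image_size = c(1944L, 2592L),
                         centre_world = c(0, 0)) {
  camera_model(scale, image_size, centre_world, kind = "macro")
}

#' @rdname camera_model
#' @param z_range not used by the constructor directly; see [autofocus()].
#' @export
micro_camera <- function(scale = 1.09, image_size = c(1440L, 1440L),
                         centre_world = c(0, 0), focus_z = 0,
                         defocus_gain = 0.02) {
  camera_model(scale, image_size, centre_world, focus_z = focus_z,
               defocus_gain = defocus_gain, kind = "micro")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model: %s, %.2f um/pxl, %d x %d, centred on (%.2f, %.2f) mm>\n",
              x$kind, x$scale, x$image_size[1], x$image_size[2],
              x$centre_world[1], x$centre_world[2]))
  invisible(x)
}

# sensor centre in 0-based pixel coordinates c(px, py)
sensor_centre_px <- function(camera) {
  c((camera$image_size[2] - 1) / 2, (camera$image_size[1] - 1) / 2)
}

#' Convert between world (mm) and pixel coordinates
#'
#' `world_to_pixel()` maps world points (mm, y up) into 0-based pixel
#' coordinates `(x = column, y = row, y down)`; `pixel_to_world()` is its
#' exact inverse. Both accept a length-2 vector or an n x 2 matrix.
#'
#' @param camera a [camera_model()].
#' @param xy world points, length-2 vector or n x 2 matrix (mm).
#' @param px pixel points, length-2 vector or n x 2 matrix (0-based).
#' @return A vector or matrix of the same shape as the input.
#' @export
world_to_pixel <- function(camera, xy) {
  v <- is.null(dim(xy))
  xy <- rbind_as_matrix(xy)
  ctr <- sensor_centre_px(camera)
  mm_per_px <- camera$scale / 1000
  px <- cbind(ctr[1] + (xy[, 1] - camera$centre_world[1]) / mm_per_px,
              ctr[2] - (xy[, 2] - camera$centre_world[2]) / mm_per_px)
  colnames(px) <- c("x", "y")
  if (v) px[1, ] else px
}

#' @rdname world_to_pixel
#' @export
pixel_to_world <- function(camera, px) {
  v <- is.null(dim(px))
  px <- rbind_as_matrix(px)
  ctr <- sensor_centre_px(camera)
  mm_per_px <- camera$scale / 1000
  xy <- cbind(camera$centre_world[1] + (px[, 1] - ctr[1]) * mm_per_px,
              camera$centre_world[2] - (px[, 2] - ctr[2]) * mm_per_px)
  colnames(xy) <- c("x", "y")
  if (v) xy[1, ] else xy
}

rbind_as_matrix <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 2) else {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
}
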