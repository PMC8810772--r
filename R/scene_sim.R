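#' Strain motility models
#'
#' Parameterizes the per-strain persistent random walk used to generate
#' synthetic worm trajectories. The walk is the minimal motion model that
#' yields strain-separable displacement-module distributions: at each
#' time step the heading relaxes toward a fresh uniform angle with weight
#' `1 - heading_persistence`, the worm pauses (zero displacement) with
#' probability `pause_prob`, and otherwise advances by
#' `speed * dt` where the speed is drawn from a Gamma distribution with
#' mean `speed_scale` (shape 4, so the mean per-step displacement over
#' moving steps is exactly `speed_scale * dt`).
#'
#' @param name strain label.
#' @param speed_scale mean crawl speed, micrometres per second (>= 0).
#' @param pause_prob probability per time step of zero displacement, in
#'   `[0, 1]`.
#' @param heading_persistence weight in `[0, 1]` of the previous heading
#'   against a fresh uniform random angle (1 = straight crawling,
#'   0 = uncorrelated tumbling).
#' @param speed_shape Gamma shape of the speed draw (mean is always
#'   `speed_scale`); larger values give steadier crawling.
#' @return An object of class `strain_model`.
#' @seealso [strain_presets()] for the three stock strains,
#'   [simulate_trajectories()].
#' @export
strain_model <- function(name, speed_scale, pause_prob = 0,
                         heading_persistence = 0.9, speed_shape = 4) {
  if (!is.numeric(speed_scale) || speed_scale < 0)
    stop("invalid-parameter: 'speed_scale' must be >= 0")
  if (pause_prob < 0 || pause_prob > 1)
    stop("invalid-parameter: 'pause_prob' must be in [0, 1]")
  if (heading_persistence < 0 || heading_persistence > 1)
    stop("invalid-parameter: 'heading_persistence' must be in [0, 1]")
  structure(list(name = as.character(name), speed_scale = speed_scale,
                 pause_prob = pause_prob,
                 heading_persistence = heading_persistence,
                 speed_shape = speed_shape),
            class = "strain_model")
}

#' Stock strain motility presets
#'
#' Three synthetic stand-ins spanning the motility range of a wild-type
#' reference, a mild locomotor deficit (25% reduced speed scale, slightly
#' more pausing) and a severely uncoordinated mutant (low speed, frequent
#' pauses, poor heading persistence). Magnitudes are free parameters of the
#' simulator chosen to be realistic for young-adult crawling on agar
#' (roughly 100-300 um/s for healthy animals); they are stand-ins, not
#' calibrations to any particular real strain.
#'
#' @param which one or more of `"wild_type"`, `"mild_deficit"`,
#'   `"severe_unc"`; defaults to all three.
#' @return A named list of [strain_model()] objects.
#' @export
strain_presets <- function(which = c("wild_type", "mild_deficit", "severe_unc")) {
  all <- list(
    wild_type    = strain_model("wild_type",    speed_scale = 150,
                                pause_prob = 0.35, heading_persistence = 0.90),
    mild_deficit = strain_model("mild_deficit", speed_scale = 112.5,
                                pause_prob = 0.40, heading_persistence = 0.90),
    severe_unc   = strain_model("severe_unc",   speed_scale = 40,
                                pause_prob = 0.75, heading_persistence = 0.50)
  )
  which <- match.arg(which, several.ok = TRUE)
  all[which]
}

#' @export
print.strain_model <- function(x, ...) {
  cat(sprintf("<strain_model '%s': %.1f um/s, pause %.2f, persistence %.2f>\n",
              x$name, x$speed_scale, x$pause_prob, x$heading_persistence))
  invisible(x)
}

# run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards; identical seed => identical draws.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Simulate ground-truth worm trajectories on a plate
#'
#' Generates a persistent-random-walk trajectory for `n_worms_per_model`
#' worms of each supplied strain on a circular plate with a reflecting
#' boundary (worms bounce off the dish wall, so the population size is
#' constant as in a walled dish). The same seed and parameters always
#' reproduce the identical scene.
#'
#' @param models a [strain_model()] or list of them.
#' @param n_worms_per_model worms per strain (>= 0).
#' @param duration scene length in seconds.
#' @param dt time step in seconds (> 0); each trajectory has
#'   `duration/dt + 1` positions.
#' @param plate_radius plate radius in mm (default 27.5, a standard 55 mm
#'   dish).
#' @param body_length worm body length, mm.
#' @param body_width worm body width, micrometres.
#' @param seed integer seed for the scene's private RNG stream.
#' @return An object of class `plate_scene`: a list with `plate_radius`,
#'   `duration`, `dt`, `times` and `worms` (one element per worm with
#'   `worm_id`, `strain`, `positions` (n x 2 mm), `headings` (rad),
#'   `body_length`, `body_width`).
#' @examples
#' sc <- simulate_trajectories(strain_presets("wild_type"), 3,
#'                             duration = 10, dt = 0.5, seed = 1)
#' sc
#' @export
simulate_trajectories <- function(models, n_worms_per_model,
                                  duration = 30, dt = 0.5,
                                  plate_radius = 27.5,
                                  body_length = 1.0, body_width = 80,
                                  seed = 1) {
  if (inherits(models, "strain_model")) models <- list(models)
  if (!length(models) || !all(vapply(models, inherits, TRUE, "strain_model")))
    stop("invalid-parameter: 'models' must be strain_model objects")
  if (dt <= 0) stop("invalid-parameter: 'dt' must be > 0")
  if (duration <= 0) stop("invalid-parameter: 'duration' must be > 0")
  if (n_worms_per_model < 0)
    stop("invalid-parameter: 'n_worms_per_model' must be >= 0")

  n_steps <- round(duration / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  # keep the whole body inside the dish
  r_eff <- plate_radius - body_length / 2

  worms <- with_seed(seed, {
    out <- list()
    wid <- 0L
    for (m in models) {
      for (i in seq_len(n_worms_per_model)) {
        wid <- wid + 1L
        out[[wid]] <- simulate_one_worm(m, wid, n_steps, dt, r_eff,
                                        body_length, body_width)
      }
    }
    out
  })

  structure(list(plate_radius = plate_radius, duration = duration, dt = dt,
                 times = times, worms = worms,
                 models = lapply(models, unclass), seed = seed),
            class = "plate_scene")
}

simulate_one_worm <- function(model, worm_id, n_steps, dt, r_eff,
                              body_length, body_width) {
  pos <- matrix(0, n_steps + 1, 2)
  head <- numeric(n_steps + 1)
  # start uniformly inside 80% of the usable radius
  r0 <- r_eff * 0.8 * sqrt(runif(1))
  a0 <- runif(1, -pi, pi)
  pos[1, ] <- c(r0 * cos(a0), r0 * sin(a0))
  head[1] <- runif(1, -pi, pi)
  mm_per_um <- 1e-3
  for (k in seq_len(n_steps)) {
    h <- head[k]
    u <- runif(1, -pi, pi)
    h <- wrap_angle(h + (1 - model$heading_persistence) * wrap_angle(u - h))
    paused <- model$pause_prob > 0 && runif(1) < model$pause_prob
    step_mm <- if (paused || model$speed_scale == 0) 0 else {
      sh <- model$speed_shape
      speed <- model$speed_scale * rgamma(1, shape = sh, rate = sh)
      speed * dt * mm_per_um
    }
    p <- pos[k, ] + step_mm * c(cos(h), sin(h))
    # reflecting dish wall
    r <- sqrt(sum(p^2))
    if (r > r_eff) {
      p <- p * (2 * r_eff - r) / r
      phi <- atan2(p[2], p[1])
      h <- wrap_angle(2 * phi + pi - h)
    }
    pos[k + 1, ] <- p
    head[k + 1] <- h
  }
  list(worm_id = worm_id, strain = model$name, positions = pos,
       headings = head, body_length = body_length, body_width = body_width)
}

#' @export
print.plate_scene <- function(x, ...) {
  cat(sprintf("<plate_scene: %d worms, %.0f s at dt = %.2g s, radius %.1f mm>\n",
              length(x$worms), x$duration, x$dt, x$plate_radius))
  strains <- table(vapply(x$worms, `[[`, "", "strain"))
  if (length(strains))
    cat("  strains:", paste(sprintf("%s=%d", names(strains), strains),
                            collapse = ", "), "\n")
  invisible(x)
}

# index of the scene instant at time t (error if outside the scene)
scene_time_index <- function(scene, t, tol = 1e-9) {
  if (t < -tol || t > scene$duration + tol)
    stop("invalid-parameter: 't' outside scene duration")
  k <- round(t / scene$dt)
  k <- max(0, min(length(scene$times) - 1, k))
  k + 1L
}

#' Ground-truth worm positions at a scene instant
#'
#' @param scene a [simulate_trajectories()] scene.
#' @param t time in seconds (snapped to the nearest scene instant).
#' @return A data frame with `worm_id`, `strain`, `x_mm`, `y_mm`,
#'   `heading_rad`.
#' @export
scene_positions <- function(scene, t) {
  k <- scene_time_index(scene, t)
  if (!length(scene$worms))
    return(data.frame(worm_id = integer(), strain = character(),
                      x_mm = numeric(), y_mm = numeric(),
                      heading_rad = numeric()))
  do.call(rbind, lapply(scene$worms, function(w)
    data.frame(worm_id = w$worm_id, strain = w$strain,
               x_mm = w$positions[k, 1], y_mm = w$positions[k, 2],
               heading_rad = w$headings[k])))
}

#' Trajectory CSV round-trip
#'
#' Scenes serialize to/from long-format CSV with columns
#' `worm_id, strain, t, x_mm, y_mm, heading_rad` plus scene geometry kept in
#' a `# key=value` comment header.
#'
#' @param scene a `plate_scene`.
#' @param path CSV file path.
#' @return `read_trajectories()` returns a `plate_scene` equal to the one
#'   written (worm body dimensions and geometry included).
#' @export
write_trajectories <- function(scene, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# %s=%s",
                 c("plate_radius", "duration", "dt", "body_length", "body_width"),
                 c(scene$plate_radius, scene$duration, scene$dt,
                   if (length(scene$worms)) scene$worms[[1]]$body_length else 1,
                   if (length(scene$worms)) scene$worms[[1]]$body_width else 80))
  writeLines(hdr, con)
  rows <- lapply(scene$worms, function(w)
    data.frame(worm_id = w$worm_id, strain = w$strain, t = scene$times,
               x_mm = w$positions[, 1], y_mm = w$positions[, 2],
               heading_rad = w$headings))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(worm_id = integer(), strain = character(), t = numeric(),
               x_mm = numeric(), y_mm = numeric(), heading_rad = numeric())
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "="))
  meta <- as.list(as.numeric(kv[, 2]))
  names(meta) <- kv[, 1]
  df <- read.csv(textConnection(lines[!grepl("^#", lines)]))
  worms <- lapply(split(df, df$worm_id), function(d) {
    d <- d[order(d$t), ]
    list(worm_id = d$worm_id[1], strain = as.character(d$strain[1]),
         positions = cbind(d$x_mm, d$y_mm), headings = d$heading_rad,
         body_length = meta$body_length, body_width = meta$body_width)
  })
  names(worms) <- NULL
  worms <- worms[order(vapply(worms, `[[`, 0, "worm_id"))]
  times <- sort(unique(df$t))
  structure(list(plate_radius = meta$plate_radius, duration = meta$duration,
                 dt = meta$dt,
                 times = if (length(times)) times else
                   seq(0, meta$duration, by = meta$dt),
                 worms = worms, models = NULL, seed = NA_integer_),
            class = "plate_scene")
}
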