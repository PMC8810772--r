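#' Segmentation and tracking parameters
#'
#' @param window adaptive-threshold neighbourhood side, pixels (odd, >= 3).
#' @param offset threshold offset below the local mean, grey levels.
#' @param min_area,max_area component area gate, pixels^2.
#' @param max_jump identity-association gate: the largest per-frame centroid
#'   displacement, pixels, still accepted as the same worm. The default of
#'   three times the expected per-frame travel of a fast worm
#'   (300 um/s at 1 fps) is computed from the camera scale by
#'   [default_segmentation_params()].
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(window = 15, offset = 10,
                                min_area = 20, max_area = 600,
                                max_jump = 33) {
  if (window < 3 || window %% 2 == 0)
    stop("invalid-parameter: 'window' must be odd and >= 3")
  if (min_area >= max_area)
    stop("invalid-parameter: need min_area < max_area")
  structure(list(window = as.integer(window), offset = offset,
                 min_area = min_area, max_area = max_area,
                 max_jump = max_jump),
            class = "segmentation_params")
}

#' @rdname segmentation_params
#' @param camera the macro [camera_model()] the parameters should suit.
#' @param body_length,body_width worm dimensions (mm, um).
#' @param max_speed fastest expected crawl, um/s.
#' @param frame_interval macro frame interval, s.
#' @export
default_segmentation_params <- function(camera, body_length = 1.0,
                                        body_width = 80, max_speed = 300,
                                        frame_interval = 1) {
  len_px <- body_length * 1000 / camera$scale
  wid_px <- max(body_width / camera$scale, 1)
  area <- len_px * wid_px
  win <- max(5, round(len_px) * 2 + 1)
  if (win %% 2 == 0) win <- win + 1
  win <- min(win, min(camera$image_size) - (min(camera$image_size) + 1) %% 2)
  segmentation_params(window = win, offset = 10,
                      min_area = max(1, 0.2 * area), max_area = 6 * area,
                      max_jump = 3 * max_speed * frame_interval / camera$scale)
}

# exact w x w box mean with replicate borders, via integral images
box_mean <- function(px, w) {
  h <- w %/% 2
  nr <- nrow(px); nc <- ncol(px)
  ri <- pmin(pmax(seq_len(nr + 2 * h) - h, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * h) - h, 1L), nc)
  pad <- px[ri, ci, drop = FALSE]
  s <- apply(pad, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  s <- rbind(0, cbind(0, s))
  i0 <- seq_len(nr); j0 <- seq_len(nc)
  (s[i0 + w, j0 + w] - s[i0, j0 + w] - s[i0 + w, j0] + s[i0, j0]) / w^2
}

# 8-connected labelling: EBImage::bwlabel (4-connected) plus a union-find
# merge of diagonally touching labels
label_components <- function(binary) {
  lab <- EBImage::bwlabel(binary * 1)
  lab <- matrix(as.integer(round(lab)), nrow(binary), ncol(binary))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  diag_pairs <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(pr))) union_(pr[i, 1], pr[i, 2])
    }
  }
  diag_pairs(lab[-nr, -nc], lab[-1, -1])   # down-right diagonal
  diag_pairs(lab[-nr, -1], lab[-1, -nc])   # down-left diagonal
  roots <- vapply(seq_len(n), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Adaptive-threshold segmentation of a macro frame
#'
#' A pixel is foreground iff its grey level is below the local mean over a
#' `window x window` neighbourhood minus `offset` (worms are darker than
#' the backlight). The local mean adapts to illumination gradients that
#' would defeat any single global threshold. Connected components are
#' labelled with 8-connectivity.
#'
#' @param frame a macro [rig_frame()].
#' @param params a [segmentation_params()].
#' @return An integer label matrix (0 = background, 1..n = components),
#'   with the logical foreground mask as attribute `"mask"`.
#' @export
segment_adaptive <- function(frame, params = segmentation_params()) {
  px <- frame$pixels
  if (!length(px)) stop("invalid-parameter: empty frame")
  w <- params$window
  if (w > min(dim(px)))
    stop("invalid-parameter: 'window' larger than the image")
  local_mean <- box_mean(px, w)
  mask <- px < local_mean - params$offset
  labels <- label_components(mask)
  attr(labels, "mask") <- mask
  labels
}

#' Size classification of segmented components
#'
#' Keeps connected components whose pixel area lies within the configured
#' gate and summarizes each as a detection (area, 0-based centroid,
#' bounding box).
#'
#' @param labels a label matrix from [segment_adaptive()] (a logical mask
#'   is accepted and labelled first).
#' @param params a [segmentation_params()].
#' @param frame_t detection timestamp to record, seconds.
#' @return A data frame of detections: `cx`, `cy` (0-based pixels), `area`
#'   (pixels^2), `x0`, `x1`, `y0`, `y1` (bounding box), `frame_t`.
#' @export
classify_by_size <- function(labels, params = segmentation_params(),
                             frame_t = NA_real_) {
  if (is.logical(labels)) labels <- label_components(labels)
  empty <- data.frame(cx = numeric(), cy = numeric(), area = numeric(),
                      x0 = numeric(), x1 = numeric(), y0 = numeric(),
                      y1 = numeric(), frame_t = numeric())
  n <- max(labels, 0)
  if (n == 0) return(empty)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  area <- tabulate(lab, nbins = n)
  keep <- which(area >= params$min_area & area <= params$max_area)
  if (!length(keep)) return(empty)
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  out <- do.call(rbind, lapply(keep, function(l) {
    s <- lab == l
    data.frame(cx = mean(xs[s]), cy = mean(ys[s]), area = area[l],
               x0 = min(xs[s]), x1 = max(xs[s]),
               y0 = min(ys[s]), y1 = max(ys[s]), frame_t = frame_t)
  }))
  rownames(out) <- NULL
  out
}

#' Minimum-distance identity association
#'
#' Assigns current detections to previously tracked worms by the optimal
#' (minimum total Euclidean distance) bipartite matching, then applies the
#' association gate: matched pairs further apart than `max_jump` are
#' broken — the old identity is censored and the detection receives a
#' fresh identity. Worms left without a detection (e.g. two worms merging
#' into one component) are censored; identities are never reused. On equal
#' total cost, the lower worm id keeps the nearer detection.
#'
#' @param prev data frame of active worms: `worm_id`, `cx`, `cy`.
#' @param current data frame of detections (from [classify_by_size()]).
#' @param max_jump association gate, pixels.
#' @param next_id smallest identity number available for new detections.
#' @return A list with `assignment` (data frame `det` (row index into
#'   `current`), `worm_id`, `dist`, `is_new`), `censored` (worm ids lost or
#'   broken this frame) and `next_id`.
#' @export
associate_identities <- function(prev, current, max_jump = 33,
                                 next_id = NULL) {
  np <- if (is.null(prev)) 0L else nrow(prev)
  nc <- nrow(current)
  if (is.null(next_id))
    next_id <- if (np) max(prev$worm_id) + 1L else 1L
  res <- data.frame(det = integer(), worm_id = integer(), dist = numeric(),
                    is_new = logical())
  censored <- integer()
  if (np && nc) {
    prev <- prev[order(prev$worm_id), , drop = FALSE]
    cost <- outer(seq_len(np), seq_len(nc), function(i, j)
      sqrt((prev$cx[i] - current$cx[j])^2 + (prev$cy[i] - current$cy[j])^2))
    # deterministic tie-break: lower id prefers the nearer detection
    eps <- 1e-9 * cost * (seq_len(np) - 1)
    big <- max(cost) + 1
    n <- max(np, nc)
    sq <- matrix(big, n, n)
    sq[seq_len(np), seq_len(nc)] <- cost + eps
    sol <- as.integer(clue::solve_LSAP(sq))
    for (i in seq_len(np)) {
      j <- sol[i]
      if (j <= nc) {
        if (cost[i, j] <= max_jump) {
          res <- rbind(res, data.frame(det = j, worm_id = prev$worm_id[i],
                                       dist = cost[i, j], is_new = FALSE))
        } else {
          censored <- c(censored, prev$worm_id[i])
        }
      } else {
        censored <- c(censored, prev$worm_id[i])  # merge / lost
      }
    }
  } else if (np) {
    censored <- prev$worm_id
  }
  unmatched <- setdiff(seq_len(nc), res$det)
  for (j in unmatched) {
    res <- rbind(res, data.frame(det = j, worm_id = next_id, dist = NA_real_,
                                 is_new = TRUE))
    next_id <- next_id + 1L
  }
  list(assignment = res[order(res$worm_id), , drop = FALSE],
       censored = sort(censored), next_id = next_id)
}

#' Multi-worm track table
#'
#' Book-keeping for whole-plate software tracking: per-identity detection
#' history, censor flags (instants at which an identity became unreliable)
#' and the set of worms already captured at micro resolution.
#'
#' @return `new_track_table()` returns an empty `track_table`.
#' @export
new_track_table <- function() {
  structure(list(
    rows = data.frame(worm_id = integer(), t = numeric(), cx = numeric(),
                      cy = numeric(), area = numeric(), censored = logical()),
    last = data.frame(worm_id = integer(), cx = numeric(), cy = numeric()),
    censored_ids = integer(), tested = integer(), next_id = 1L
  ), class = "track_table")
}

#' @rdname new_track_table
#' @param table a `track_table`.
#' @param detections detections for one frame ([classify_by_size()]).
#' @param t frame time, seconds.
#' @param max_jump association gate, pixels.
#' @param protect worm ids that must not be censored when their detection
#'   is missing this frame (e.g. the worm currently occluded by the
#'   saturated laser spot during goal acquisition); they keep their last
#'   known position instead.
#' @return `track_update()` returns the updated table.
#' @export
track_update <- function(table, detections, t, max_jump = 33,
                         protect = integer()) {
  assoc <- associate_identities(table$last, detections, max_jump,
                                table$next_id)
  carried <- intersect(assoc$censored, protect)
  assoc$censored <- setdiff(assoc$censored, protect)
  a <- assoc$assignment
  if (nrow(a)) {
    table$rows <- rbind(table$rows, data.frame(
      worm_id = a$worm_id, t = t,
      cx = detections$cx[a$det], cy = detections$cy[a$det],
      area = detections$area[a$det], censored = FALSE))
  }
  if (length(assoc$censored)) {
    table$rows <- rbind(table$rows, data.frame(
      worm_id = assoc$censored, t = t, cx = NA_real_, cy = NA_real_,
      area = NA_real_, censored = TRUE))
    table$censored_ids <- sort(union(table$censored_ids, assoc$censored))
  }
  last <- if (nrow(a))
    data.frame(worm_id = a$worm_id, cx = detections$cx[a$det],
               cy = detections$cy[a$det]) else
    data.frame(worm_id = integer(), cx = numeric(), cy = numeric())
  if (length(carried)) {
    keep <- table$last[table$last$worm_id %in% carried, , drop = FALSE]
    last <- rbind(last, keep)
    last <- last[order(last$worm_id), , drop = FALSE]
  }
  table$last <- last
  table$next_id <- assoc$next_id
  table
}

#' @rdname new_track_table
#' @param frames list of macro [rig_frame()]s in time order.
#' @param params a [segmentation_params()].
#' @return `track_frames()` segments, size-classifies and associates every
#'   frame and returns the resulting `track_table`.
#' @export
track_frames <- function(frames, params = segmentation_params()) {
  table <- new_track_table()
  for (f in frames) {
    det <- classify_by_size(segment_adaptive(f, params), params,
                            frame_t = f$t)
    table <- track_update(table, det, f$t, params$max_jump)
  }
  table
}

#' @export
print.track_table <- function(x, ...) {
  ids <- unique(x$rows$worm_id)
  cat(sprintf("<track_table: %d identities, %d detections, %d censored, %d tested>\n",
              length(ids), sum(!x$rows$censored), length(x$censored_ids),
              length(x$tested)))
  invisible(x)
}

#' @export
as.data.frame.track_table <- function(x, ...) x$rows

#' Track-table CSV round-trip
#'
#' Serialized as `worm_id, t, cx_pxl, cy_pxl, area, censored` (censor rows
#' carry empty coordinates); tested ids in a `# tested=` header comment.
#'
#' @param table a [new_track_table()].
#' @param path CSV path.
#' @export
write_track_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tested=%s", paste(table$tested, collapse = ";")), con)
  df <- table$rows
  names(df) <- c("worm_id", "t", "cx_pxl", "cy_pxl", "area", "censored")
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_table
#' @export
read_track_table <- function(path) {
  lines <- readLines(path)
  tested <- integer()
  hdr <- grep("^# tested=", lines, value = TRUE)
  if (length(hdr)) {
    v <- sub("^# tested=", "", hdr[1])
    if (nzchar(v)) tested <- as.integer(strsplit(v, ";")[[1]])
  }
  df <- read.csv(textConnection(lines[!grepl("^#", lines)]))
  table <- new_track_table()
  table$rows <- data.frame(worm_id = df$worm_id, t = df$t, cx = df$cx_pxl,
                           cy = df$cy_pxl, area = df$area,
                           censored = as.logical(df$censored))
  table$censored_ids <- sort(unique(df$worm_id[df$censored]))
  table$tested <- tested
  live <- df[!df$censored, ]
  if (nrow(live)) {
    last <- live[order(live$t), ]
    last <- last[!duplicated(last$worm_id, fromLast = TRUE), ]
    table$last <- data.frame(worm_id = last$worm_id, cx = last$cx_pxl,
                             cy = last$cy_pxl)
    table$last <- table$last[!table$last$worm_id %in% table$censored_ids, ]
  }
  table$next_id <- if (nrow(df)) max(df$worm_id) + 1L else 1L
  table
}
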