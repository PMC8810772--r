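# Desk-scale rig used across tests: a coarse macro camera and a small worm
# so full image-in-the-loop sessions stay fast. The geometry is scaled, not
# simplified: all transforms, thresholds and ratios behave as at full scale.

desk_macro <- function() macro_camera(scale = 110, image_size = c(512L, 512L))

desk_micro <- function(focus_z = 20)
  micro_camera(image_size = c(800L, 800L), focus_z = focus_z)

desk_scene <- function(models = strain_presets("wild_type"), n = 1,
                       duration = 40, seed = 1) {
  simulate_trajectories(models, n, duration = duration, dt = 0.5,
                        body_length = 0.5, body_width = 60, seed = seed)
}

desk_config <- function(..., focus_z = 20) {
  macro <- desk_macro()
  controller_config(
    macro_cam = macro, micro_cam = desk_micro(focus_z),
    seg_params = default_segmentation_params(macro, body_length = 0.5,
                                             body_width = 60),
    z_candidates = focus_z + seq(-40, 40, by = 20), ...)
}

# brute-force minimum-cost complete assignment of min(n, m) pairs by
# enumerating permutations (independent oracle for associate_identities)
brute_force_assignment <- function(cost) {
  np <- nrow(cost); nc <- ncol(cost)
  if (np <= nc) {
    perms <- perms_of(nc, np)
    best <- Inf; best_map <- NULL
    for (i in seq_len(nrow(perms))) {
      tot <- sum(cost[cbind(seq_len(np), perms[i, ])])
      if (tot < best) { best <- tot; best_map <- perms[i, ] }
    }
    list(cost = best, map = best_map)   # map[i] = detection for prev i
  } else {
    r <- brute_force_assignment(t(cost))
    map <- rep(NA_integer_, np)
    map[r$map] <- seq_len(nc)
    list(cost = r$cost, map = map)
  }
}

perms_of <- function(n, k) {
  if (k == 0) return(matrix(integer(), 1, 0))
  out <- NULL
  for (cmb in utils::combn(n, k, simplify = FALSE)) {
    p <- permutations_all(cmb)
    out <- rbind(out, p)
  }
  out
}

permutations_all <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], permutations_all(v[-i])))
  out
}

# independent exact two-sided rank-sum p-value by direct enumeration of the
# Mann-Whitney U statistic (counts of pairs a_i > b_j, halves for ties)
enumerate_rank_sum_p <- function(a, b) {
  pool <- c(a, b); n <- length(a); N <- length(pool)
  u_stat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(a, b)
  us <- utils::combn(N, n, function(idx) u_stat(pool[idx], pool[-idx]))
  min(1, 2 * min(mean(us <= obs + 1e-9), mean(us >= obs - 1e-9)))
}
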