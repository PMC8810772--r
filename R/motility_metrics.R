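#' Displacement-module series
#'
#' The module index of a tracked worm is the per-instant Euclidean
#' displacement magnitude
#' `M_k = sqrt((x_k - x_{k-1})^2 + (y_k - y_{k-1})^2)`,
#' computed from the mechanical-tracking control actions (motor steps; at
#' the default rig pitch one step is 1.09 um). A `module_series` holds one
#' worm's modules plus its identity and strain label.
#'
#' @param x either an n x 2 matrix / data frame of positions `(x_k, y_k)`
#'   (n >= 2), or of per-instant shifts `(dx_k, dy_k)` (n >= 1), in steps.
#' @param input `"positions"` (differences are taken) or `"deltas"` (rows
#'   are already per-instant shifts).
#' @param worm_id worm identity label.
#' @param strain strain label.
#' @return An object of class `module_series`: list with `worm_id`,
#'   `strain`, `modules` (numeric, all >= 0, one per instant).
#' @examples
#' displacement_modules(rbind(c(0, 0), c(3, 4)))$modules  # 5
#' @export
displacement_modules <- function(x, input = c("positions", "deltas"),
                                 worm_id = NA_integer_,
                                 strain = NA_character_) {
  input <- match.arg(input)
  x <- rbind_as_matrix(x)
  if (nrow(x) == 0)
    stop("invalid-parameter: empty input")
  d <- if (input == "positions") {
    if (nrow(x) < 2)
      stop("invalid-parameter: need at least 2 positions")
    apply(x, 2, diff)
  } else x
  d <- rbind_as_matrix(d)
  structure(list(worm_id = worm_id, strain = strain,
                 modules = sqrt(d[, 1]^2 + d[, 2]^2)),
            class = "module_series")
}

#' @export
print.module_series <- function(x, ...) {
  cat(sprintf("<module_series: worm %s (%s), %d instants, sum %.1f steps>\n",
              x$worm_id, x$strain, length(x$modules), sum(x$modules)))
  invisible(x)
}

as_series_list <- function(x) {
  if (inherits(x, "module_series")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "module_series"))) x
  else stop("invalid-parameter: expected module_series object(s)")
}

#' Per-worm module-sum percentage
#'
#' Sums each worm's modules (the total amount of movement of that worm over
#' its capture) and expresses the sums as percentages. The default base is
#' the maximum per-worm sum in the experiment (the most mobile worm is
#' 100%); `base = "total"` normalizes to the group total instead.
#'
#' @param series a `module_series` or list of them.
#' @param base `"max"` (default) or `"total"`.
#' @return A data frame with `worm_id`, `strain`, `module_sum`, `percent`.
#' @export
module_sum_percent <- function(series, base = c("max", "total")) {
  base <- match.arg(base)
  series <- as_series_list(series)
  if (!length(series)) stop("invalid-parameter: empty input")
  sums <- vapply(series, function(s) sum(s$modules), 0)
  denom <- if (base == "max") max(sums) else sum(sums)
  pct <- if (denom > 0) 100 * sums / denom else rep(0, length(sums))
  data.frame(worm_id = unlist(lapply(series, `[[`, "worm_id")),
             strain = unlist(lapply(series, `[[`, "strain")),
             module_sum = sums, percent = pct)
}

#' Histogram bin specification for module values
#'
#' Unit-width bins in steps starting at zero — `[0,1), [1,2), ...` — plus a
#' final overflow bin collecting everything at or above the last edge. The
#' `[0,1)` bin is kept (a module below one step means the worm is most
#' probably static).
#'
#' @param bin_edges strictly increasing finite edges (default `0:10`).
#' @return An object of class `histogram_spec`.
#' @export
histogram_spec <- function(bin_edges = 0:10) {
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop("invalid-parameter: 'bin_edges' must be strictly increasing")
  structure(list(bin_edges = as.numeric(bin_edges)), class = "histogram_spec")
}

#' Relative frequency of module values
#'
#' Bins module values and normalizes counts to relative frequencies
#' (a probability vector summing to one). Input may be a single worm's
#' series, a list of series (pooled), or a bare numeric vector.
#'
#' @param x `module_series`, list of them, or numeric module values.
#' @param spec a [histogram_spec()].
#' @return A data frame with `bin` (label), `lower`, `upper`, `count`,
#'   `freq`.
#' @export
relative_frequency <- function(x, spec = histogram_spec()) {
  m <- if (is.numeric(x)) x else
    unlist(lapply(as_series_list(x), `[[`, "modules"), use.names = FALSE)
  if (!length(m)) stop("invalid-parameter: no module values")
  e <- spec$bin_edges
  nb <- length(e) - 1L
  idx <- findInterval(m, e, left.open = FALSE)   # 0 impossible for m >= 0
  idx[idx > nb] <- nb + 1L                       # overflow bin
  counts <- tabulate(idx, nbins = nb + 1L)
  lower <- c(e[-length(e)], e[length(e)])
  upper <- c(e[-1], Inf)
  lab <- c(sprintf("[%g-%g)", head(e, -1), e[-1]),
           sprintf("[%g-Inf)", e[length(e)]))
  data.frame(bin = lab, lower = lower, upper = upper, count = counts,
             freq = counts / length(m))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two independent samples. For small
#' samples (`min(n, m) <= 8` and `n + m <= 16`) the null distribution of
#' the rank sum is enumerated exhaustively over all `choose(n+m, n)` group
#' splits of the pooled midranks (so ties are handled exactly); otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. When every value in both samples is identical the p-value is 1.
#'
#' @param a,b numeric samples (non-empty).
#' @return An object of class `htest` with the rank-sum statistic `W`
#'   (sum of ranks of `a`), the two-sided `p.value` and the branch used in
#'   `method`.
#' @examples
#' rank_sum_test(1:3, 4:6)$p.value  # 0.1
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b))
    stop("invalid-parameter: both samples must be non-empty")
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n)])
  exact <- min(n, m) <= 8 && N <= 16
  if (exact) {
    splits <- combn(N, n)
    Ws <- colSums(matrix(r[splits], nrow = n))
    p <- min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
    method <- "rank-sum, exact enumeration"
  } else {
    mu <- n * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- W - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "rank-sum, normal approximation with tie correction"
  }
  structure(list(statistic = c(W = W), p.value = p, method = method,
                 alternative = "two.sided",
                 data.name = paste(deparse1(substitute(a)), "and",
                                   deparse1(substitute(b)))),
            class = "htest")
}

#' Compare strain motility from module series
#'
#' Computes per-worm module sums, the module-sum percentage table, pooled
#' per-strain relative-frequency histograms, and all pairwise two-sided
#' rank-sum tests on the per-worm sums.
#'
#' @param groups named list: one element per strain, each a list of
#'   [displacement_modules()] series (>= 2 worms per strain, >= 2 strains).
#' @param spec a [histogram_spec()] for the per-strain histograms.
#' @param percent_base normalization base for [module_sum_percent()].
#' @return An object of class `strain_comparison` with elements `percent`
#'   (per-worm table), `histograms` (per strain), `tests` (data frame of
#'   pairwise p-values) and `sums` (named list of per-worm sums).
#' @export
compare_strains <- function(groups, spec = histogram_spec(),
                            percent_base = c("max", "total")) {
  if (length(groups) < 2)
    stop("insufficient-sample: need at least 2 strains")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("invalid-parameter: 'groups' must be a named list")
  groups <- lapply(groups, as_series_list)
  nw <- vapply(groups, length, 0L)
  if (any(nw < 2))
    stop(sprintf("insufficient-sample: strain '%s' has fewer than 2 worms",
                 names(groups)[which(nw < 2)[1]]))
  sums <- lapply(groups, function(g) vapply(g, function(s) sum(s$modules), 0))
  for (nm in names(groups))
    for (i in seq_along(groups[[nm]])) groups[[nm]][[i]]$strain <- nm
  percent <- module_sum_percent(unlist(groups, recursive = FALSE),
                                base = percent_base)
  histograms <- lapply(groups, relative_frequency, spec = spec)
  pairs <- combn(names(groups), 2)
  tests <- data.frame(
    strain_a = pairs[1, ], strain_b = pairs[2, ],
    n_a = nw[pairs[1, ]], n_b = nw[pairs[2, ]],
    p.value = apply(pairs, 2, function(p)
      rank_sum_test(sums[[p[1]]], sums[[p[2]]])$p.value),
    row.names = NULL)
  structure(list(percent = percent, histograms = histograms, tests = tests,
                 sums = sums, spec = spec),
            class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat("Strain motility comparison (displacement-module index)\n")
  cat(sprintf("  strains: %s\n",
              paste(sprintf("%s (n=%d)", names(x$sums),
                            lengths(x$sums)), collapse = ", ")))
  cat("  pairwise rank-sum tests on per-worm module sums:\n")
  t <- x$tests
  for (i in seq_len(nrow(t)))
    cat(sprintf("    %s vs %s: p = %.4g%s\n", t$strain_a[i], t$strain_b[i],
                t$p.value[i], if (t$p.value[i] < 0.05) " *" else ""))
  invisible(x)
}

#' @export
summary.strain_comparison <- function(object, ...) {
  med <- vapply(object$sums, stats::median, 0)
  f0 <- vapply(object$histograms, function(h) h$freq[1], 0)
  out <- data.frame(strain = names(object$sums), n = lengths(object$sums),
                    median_sum = med, static_bin_freq = f0,
                    row.names = NULL)
  cat("Per-strain summary (module sums in steps; static bin = [0-1)):\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' Plot per-strain relative-frequency histograms
#'
#' Grouped bars of module-value relative frequencies per strain, one group
#' per bin rank (abscissa in steps).
#'
#' @param x a [compare_strains()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.strain_comparison <- function(x, ...) {
  mat <- do.call(rbind, lapply(x$histograms, `[[`, "freq"))
  colnames(mat) <- x$histograms[[1]]$bin
  graphics::barplot(mat, beside = TRUE, legend.text = rownames(mat),
                    xlab = "module value rank (steps)",
                    ylab = "relative frequency", las = 2, ...)
  invisible(x)
}
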