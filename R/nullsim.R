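#' Disk-shaped in-silico cell of a given area
#'
#' Convenience geometry for the chance-cluster null when no real cell
#' outlines are supplied.
#'
#' @param area_um2 cell footprint in square micrometres
#' @param pixel_size um per px
#' @param n_vertices polygon resolution
#' @return a `cell_roi` centered at the origin, vertices in pixels
#' @export
chance_cell_disk <- function(area_um2 = 120, pixel_size = 0.16,
                             n_vertices = 96L) {
  r <- sqrt(area_um2 / pi) / pixel_size
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-1]
  cell_roi("null", "disk", cbind(r * cos(theta), r * sin(theta)))
}

#' Monte-Carlo null model for chance clustering
#'
#' Estimates how often clusters of each size arise when secretion is
#' spatially random (complete spatial randomness): for each event count
#' n in `n_events_grid`, n events are placed uniformly at random in
#' each in-silico cell, clustered with [cluster_cell_events()], and
#' clusters of size >= k are tallied for each k in `k_grid`. Reported
#' are per-cell means over replicates with Monte-Carlo standard errors.
#'
#' Note the default `params` uses `min_points = 2` so that chance
#' *pairs* are countable; clusters of size >= 3 under this null are the
#' quantity that justifies the >= 3-event reporting rule.
#'
#' @param cells a `cell_roi`, list of `cell_roi`, or `islet_geometry`
#' @param n_events_grid integer vector of per-cell event counts
#' @param k_grid integer vector of cluster sizes (>= 2)
#' @param params a `cluster_params` (defaults to eps 9 px, min_points 2)
#' @param replicates Monte-Carlo replicates per (cell, n) combination
#'   (>= 100)
#' @param seed integer seed
#' @return object of class `null_sim_result`: a data frame with
#'   columns n_events, k, expected (mean clusters of size >= k per
#'   cell), mc_se, plus attributes `replicates` and `seed`
#' @export
simulate_chance_clusters <- function(cells,
                                     n_events_grid = 0:40,
                                     k_grid = 2:4,
                                     params = cluster_params(min_points = 2L),
                                     replicates = 1000L, seed = NULL) {
  if (inherits(cells, "islet_geometry")) cells <- cells$cells
  if (inherits(cells, "cell_roi")) cells <- list(cells)
  if (length(n_events_grid) == 0 || length(k_grid) == 0)
    stop("empty n_events_grid or k_grid")
  if (replicates < 100) stop("need at least 100 replicates")
  if (!is.null(seed)) set.seed(seed)
  k_grid <- sort(as.integer(k_grid))
  n_events_grid <- sort(as.integer(n_events_grid))
  # counts[n, k] accumulated over cells x replicates
  acc <- array(0, dim = c(length(n_events_grid), length(k_grid),
                          length(cells) * replicates))
  for (ci in seq_along(cells)) {
    v <- cells[[ci]]$vertices
    for (r in seq_len(replicates)) {
      slot <- (ci - 1L) * replicates + r
      for (ni in seq_along(n_events_grid)) {
        n <- n_events_grid[ni]
        if (n == 0) next
        pts <- sample_in_polygon(n, v)
        lab <- cluster_cell_events(pts, params = params)
        if (any(lab > 0)) {
          sizes <- tabulate(lab)
          for (ki in seq_along(k_grid))
            acc[ni, ki, slot] <- sum(sizes >= k_grid[ki])
        }
      }
    }
  }
  out <- expand.grid(n_events = n_events_grid, k = k_grid,
                     KEEP.OUT.ATTRS = FALSE)
  out$expected <- NA_real_; out$mc_se <- NA_real_
  nrep <- dim(acc)[3]
  for (ki in seq_along(k_grid)) {
    for (ni in seq_along(n_events_grid)) {
      x <- acc[ni, ki, ]
      row <- out$n_events == n_events_grid[ni] & out$k == k_grid[ki]
      out$expected[row] <- mean(x)
      out$mc_se[row] <- stats::sd(x) / sqrt(nrep)
    }
  }
  structure(out, replicates = as.integer(replicates), seed = seed,
            class = c("null_sim_result", "data.frame"))
}

#' Smallest reportable cluster size given a chance tolerance
#'
#' Returns the smallest cluster size k whose expected number of chance
#' clusters per cell stays at or below `tolerance` across the whole
#' simulated event-count range. With the original analysis' observed
#' secretion levels this rule selects k = 3, the threshold used for all
#' hot-spot reporting.
#'
#' @param result a `null_sim_result` (or any data frame with columns
#'   n_events, k, expected)
#' @param tolerance maximum tolerated expected chance clusters per cell
#' @return the minimal k as an integer, or NA_integer_ (with a warning)
#'   if no simulated k satisfies the tolerance
#' @export
min_reportable_cluster_size <- function(result, tolerance = 0.05) {
  stopifnot(all(c("n_events", "k", "expected") %in% names(result)))
  ks <- sort(unique(result$k))
  for (k in ks) {
    worst <- max(result$expected[result$k == k], na.rm = TRUE)
    if (worst <= tolerance) return(as.integer(k))
  }
  warning("no simulated cluster size satisfies the tolerance ", tolerance)
  NA_integer_
}
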