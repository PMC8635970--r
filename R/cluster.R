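#' Clustering parameters for hot-spot identification
#'
#' Density-based scanning over the spatial coordinates of within-cell
#' events. The defaults (eps = 9 px, i.e. 1.44 um at 0.16 um/px, and a
#' minimum neighborhood of 3 events counting the point itself) match
#' the original analysis, which operated in pixel units. Set
#' `distance_space = "um"` with `eps = 1.5` for the micrometre variant.
#'
#' @param eps neighborhood search radius (px or um per `distance_space`)
#' @param min_points minimum events in an eps-neighborhood (including
#'   the point itself) for a core point; also the minimum cluster size
#' @param distance_space "pixels" or "um"
#' @return object of class `cluster_params`
#' @export
cluster_params <- function(eps = 9, min_points = 3L,
                           distance_space = c("pixels", "um")) {
  distance_space <- match.arg(distance_space)
  stopifnot(eps > 0, min_points >= 2)
  structure(list(eps = eps, min_points = as.integer(min_points),
                 distance_space = distance_space),
            class = "cluster_params")
}

#' Density-based clustering of one cell's events
#'
#' Standard DBSCAN on the 2-D event positions (time is ignored): a core
#' point has at least `min_points` events (itself included) within
#' Euclidean distance `eps`; clusters are the connected components of
#' core points (cores within eps of each other are connected) plus
#' their border points; remaining events are noise. Border points
#' reachable from more than one cluster are assigned to the cluster of
#' the earliest core point (ascending event time, then input order)
#' within eps, which makes the partition independent of input order.
#' Cluster labels are numbered by the time of each cluster's earliest
#' core point.
#'
#' @param coords n x 2 matrix of event positions (px or um, consistent
#'   with `params$eps`)
#' @param times event times in s used for the deterministic tie-break
#'   (defaults to input order)
#' @param params a `cluster_params`
#' @return integer vector of cluster labels, 0 = noise
#' @export
cluster_cell_events <- function(coords, times = NULL,
                                params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2)
  n <- nrow(coords)
  labels <- integer(n)
  if (n == 0) return(labels)
  if (is.null(times)) times <- seq_len(n)
  if (any(!is.finite(coords))) stop("event positions must be finite")
  d2 <- as.matrix(stats::dist(coords))^2
  nb <- d2 <= params$eps^2
  core <- rowSums(nb) >= params$min_points
  if (!any(core)) return(labels)
  # connected components of the core-core eps graph, explored from the
  # earliest core point outward
  comp <- integer(n)
  next_label <- 0L
  ord <- order(times, seq_len(n))
  for (i in ord) {
    if (!core[i] || comp[i] != 0L) next
    next_label <- next_label + 1L
    queue <- i
    comp[i] <- next_label
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nbrs <- which(nb[v, ] & core & comp == 0L)
      comp[nbrs] <- next_label
      queue <- c(queue, nbrs)
    }
  }
  labels[core] <- comp[core]
  # border points: non-core within eps of a core; earliest such core wins
  for (i in which(!core)) {
    cand <- which(nb[i, ] & core)
    if (length(cand) == 0) next
    first <- cand[order(times[cand], cand)][1]
    labels[i] <- comp[first]
  }
  labels
}

#' Cluster all assigned events, per cell
#'
#' Events in different cells are never co-clustered. Adds a cluster_id
#' column (integer per cell, 0 = noise / non-clustered).
#'
#' @param events assigned event data frame (needs x_px, y_px, cell_id,
#'   time_s; islet_id recommended)
#' @param params a `cluster_params`
#' @param pixel_size um per px, required when
#'   `params$distance_space == "um"`
#' @return `events` with a cluster_id column
#' @export
cluster_events <- function(events, params = cluster_params(),
                           pixel_size = attr(events, "pixel_size")) {
  n <- nrow(events)
  events$cluster_id <- integer(n)
  if (n == 0) return(events)
  scale <- 1
  if (params$distance_space == "um") {
    if (is.null(pixel_size)) stop("pixel_size needed for um clustering")
    scale <- pixel_size
  }
  key <- paste(events$islet_id, events$cell_id, sep = "\r")
  for (k in unique(key)) {
    sel <- which(key == k)
    lab <- cluster_cell_events(
      cbind(events$x_px[sel], events$y_px[sel]) * scale,
      times = events$time_s[sel], params = params)
    events$cluster_id[sel] <- lab
  }
  events
}

#' Per-cluster records
#'
#' @param events clustered event data frame (cluster_id set)
#' @return data frame with one row per cluster: islet_id, cell_id,
#'   cluster_id, size, first_time, last_time, centroid_x, centroid_y
#' @export
cluster_records <- function(events) {
  cl <- events[events$cluster_id > 0, , drop = FALSE]
  if (nrow(cl) == 0)
    return(data.frame(islet_id = character(0), cell_id = character(0),
                      cluster_id = integer(0), size = integer(0),
                      first_time = numeric(0), last_time = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0)))
  key <- interaction(cl$islet_id, cl$cell_id, cl$cluster_id, drop = TRUE)
  recs <- lapply(split(cl, key), function(s) data.frame(
    islet_id = s$islet_id[1], cell_id = s$cell_id[1],
    cluster_id = s$cluster_id[1], size = nrow(s),
    first_time = min(s$time_s), last_time = max(s$time_s),
    centroid_x = mean(s$x_px), centroid_y = mean(s$y_px)))
  out <- do.call(rbind, recs)
  out <- out[order(out$islet_id, out$cell_id, out$cluster_id), ]
  rownames(out) <- NULL
  out
}

#' Per-cell secretion summaries
#'
#' Every beta-cell in the field is a row, whether it secreted during
#' the movie or not.
#'
#' @param events clustered event data frame (cluster_id set)
#' @param rois list of `cell_roi` (or `islet_geometry`) defining the
#'   full cell population, including silent cells
#' @return data frame: islet_id, cell_id, n_events, n_clusters,
#'   n_clustered_events, n_nonclustered_events
#' @export
summarize_cells <- function(events, rois) {
  if (inherits(rois, "islet_geometry")) rois <- rois$cells
  rows <- lapply(rois, function(r) {
    sel <- events$islet_id == r$islet_id & events$cell_id == r$cell_id
    lab <- events$cluster_id[sel]
    data.frame(islet_id = r$islet_id, cell_id = r$cell_id,
               n_events = sum(sel),
               n_clusters = length(unique(lab[lab > 0])),
               n_clustered_events = sum(lab > 0),
               n_nonclustered_events = sum(lab == 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-islet secretion summaries
#'
#' Percentages of cells in each field of view with at least one
#' secretion event, with at least one cluster, and (among secreting
#' cells) with at least one cluster. The secreting-cell percentage is
#' NA when the islet has no secreting cells.
#'
#' @param cell_summaries output of [summarize_cells()]
#' @return data frame: islet_id, n_cells, pct_cells_with_event,
#'   pct_cells_with_cluster, pct_secreting_cells_with_cluster
#' @export
summarize_islets <- function(cell_summaries) {
  rows <- lapply(split(cell_summaries, cell_summaries$islet_id),
                 function(s) {
    if (nrow(s) == 0) stop("islet with zero cells")
    n <- nrow(s)
    n_ev <- sum(s$n_events > 0)
    n_cl <- sum(s$n_clusters > 0)
    data.frame(islet_id = s$islet_id[1], n_cells = n,
               pct_cells_with_event = 100 * n_ev / n,
               pct_cells_with_cluster = 100 * n_cl / n,
               pct_secreting_cells_with_cluster =
                 if (n_ev > 0) 100 * n_cl / n_ev else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
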