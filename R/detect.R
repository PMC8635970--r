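#' Detection configuration
#'
#' Constants of the flash-identification chain: frames are pairwise
#' subtracted, grouped into non-overlapping max projections, then
#' thresholded local maxima are reported as events. The defaults
#' (intensity threshold 5000 counts, search range 6 px, groups of 5
#' frames at 60 ms, i.e. 300 ms analyzed resolution) match the original
#' ImageJ macro settings.
#'
#' @param noise_level intensity threshold in counts
#' @param search_range local-maximum search radius in pixels
#' @param group_size frames per max projection
#' @param frame_interval seconds per raw frame
#' @param min_separation suppression radius between reported events in
#'   one frame (defaults to `search_range`)
#' @return object of class `detection_config`
#' @export
detection_config <- function(noise_level = 5000, search_range = 6L,
                             group_size = 5L, frame_interval = 0.06,
                             min_separation = search_range) {
  stopifnot(noise_level > 0, search_range >= 1, group_size >= 1,
            frame_interval > 0)
  structure(list(noise_level = noise_level,
                 search_range = as.integer(search_range),
                 group_size = as.integer(group_size),
                 frame_interval = frame_interval,
                 min_separation = min_separation),
            class = "detection_config")
}

#' Frame-by-frame difference stack
#'
#' Subtracts each frame from the next in signed floating point;
#' negative values are preserved (not clamped).
#'
#' @param movie numeric array (ny, nx, F), F >= 2
#' @return numeric array (ny, nx, F - 1); frame i = frame(i+1) - frame(i)
#' @export
difference_stack <- function(movie) {
  f <- dim(movie)[3]
  if (is.na(f) || f < 2) stop("difference_stack needs at least 2 frames")
  out <- array(0, dim = c(dim(movie)[1], dim(movie)[2], f - 1L))
  for (i in seq_len(f - 1L)) # frame-wise to keep peak memory low
    out[, , i] <- movie[, , i + 1L] - movie[, , i]
  attr(out, "frame_interval") <- attr(movie, "frame_interval")
  out
}

#' Grouped maximum projection through time
#'
#' Reduces consecutive non-overlapping groups of `group_size` frames by
#' the per-pixel maximum; a final partial group is projected as-is. At
#' the defaults (5 frames of 60 ms) the projected stack has an
#' effective frame interval of 300 ms.
#'
#' @param stack numeric array (ny, nx, F)
#' @param group_size frames per group
#' @return numeric array (ny, nx, ceiling(F / group_size)) with
#'   attribute `frame_interval` multiplied by `group_size`
#' @export
group_max_project <- function(stack, group_size = 5L) {
  f <- dim(stack)[3]
  if (is.na(f) || f < 1) stop("empty stack")
  stopifnot(group_size >= 1)
  group_size <- as.integer(group_size)
  n_out <- ceiling(f / group_size)
  out <- array(0, dim = c(dim(stack)[1], dim(stack)[2], n_out))
  for (g in seq_len(n_out)) {
    idx <- ((g - 1L) * group_size + 1L):min(g * group_size, f)
    if (length(idx) == 1L) {
      out[, , g] <- stack[, , idx]
    } else {
      out[, , g] <- apply(stack[, , idx, drop = FALSE], c(1, 2), max)
    }
  }
  fi <- attr(stack, "frame_interval")
  attr(out, "frame_interval") <- if (is.null(fi)) NULL else fi * group_size
  out
}

#' Detect secretion flashes in a projected difference stack
#'
#' Per frame, pixels above `noise_level` are candidates; greedy
#' non-maximum suppression keeps, in descending intensity order, the
#' candidates with no stronger kept candidate within `search_range`
#' pixels (Euclidean). Each kept candidate becomes one event with an
#' intensity-weighted centroid over the (2 * search_range + 1)^2 window
#' (negative residuals are ignored in the weighting; the window is
#' clipped at field borders). A flash is reported once: a candidate is
#' suppressed if an event was already reported within `search_range`
#' pixels in the immediately preceding projected frame.
#'
#' @param stack projected difference stack (ny, nx, frames); its
#'   `frame_interval` attribute (or `group_size * frame_interval` from
#'   `config`) sets the event time base
#' @param config a `detection_config`
#' @return event data frame: time_s, x_px, y_px (centroid), frame
#'   (0-based), peak_x, peak_y (suppression peak, integer px),
#'   peak_intensity, islet_id, cell_id, cluster_id (the latter three
#'   unassigned)
#' @export
detect_flashes <- function(stack, config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  eff_dt <- attr(stack, "frame_interval")
  if (is.null(eff_dt)) eff_dt <- config$frame_interval * config$group_size
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nf <- dim(stack)[3]
  r <- config$search_range
  out <- list()
  prev_xy <- matrix(numeric(0), ncol = 2)
  for (f in seq_len(nf)) {
    frame <- stack[, , f]
    idx <- which(frame > config$noise_level, arr.ind = TRUE)
    kx <- ky <- numeric(0); ghost <- logical(0)
    if (nrow(idx) > 0) {
      vals <- frame[idx]
      ord <- order(vals, decreasing = TRUE)
      idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]
      for (i in seq_len(nrow(idx))) {
        x <- idx[i, 2] - 1; y <- idx[i, 1] - 1
        if (length(kx) > 0 &&
            min((kx - x)^2 + (ky - y)^2) <= config$min_separation^2) next
        if (nrow(prev_xy) > 0 &&
            min((prev_xy[, 1] - x)^2 + (prev_xy[, 2] - y)^2) <= r^2) {
          # residual of a flash reported in the previous frame: not
          # reported again, but still suppresses weaker neighbors
          kx <- c(kx, x); ky <- c(ky, y); ghost <- c(ghost, TRUE)
          next
        }
        kx <- c(kx, x); ky <- c(ky, y); ghost <- c(ghost, FALSE)
        # intensity-weighted centroid over the clipped window
        xs <- max(0, x - r):min(nx - 1, x + r)
        ys <- max(0, y - r):min(ny - 1, y + r)
        w <- pmax(frame[ys + 1, xs + 1, drop = FALSE], 0)
        sw <- sum(w)
        if (sw > 0) {
          cx <- sum(w * matrix(xs, nrow(w), ncol(w), byrow = TRUE)) / sw
          cy <- sum(w * matrix(ys, nrow(w), ncol(w))) / sw
        } else {
          cx <- x; cy <- y
        }
        out[[length(out) + 1]] <- data.frame(
          time_s = (f - 1) * eff_dt, x_px = cx, y_px = cy, frame = f - 1L,
          peak_x = x, peak_y = y, peak_intensity = vals[i])
      }
    }
    prev_xy <- cbind(kx[!ghost], ky[!ghost])
  }
  ev <- if (length(out) == 0) {
    data.frame(time_s = numeric(0), x_px = numeric(0), y_px = numeric(0),
               frame = integer(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_intensity = numeric(0))
  } else {
    do.call(rbind, out)
  }
  ev$islet_id <- rep(NA_character_, nrow(ev))
  ev$cell_id <- rep(NA_character_, nrow(ev))
  ev$cluster_id <- rep(NA_integer_, nrow(ev))
  attr(ev, "frame_interval") <- eff_dt
  ev
}

#' Full detection chain: difference, grouped projection, flash search
#'
#' @param movie raw movie stack (ny, nx, F)
#' @param config a `detection_config`
#' @return event data frame as from [detect_flashes()]
#' @export
detect_events <- function(movie, config = detection_config()) {
  d <- difference_stack(movie)
  if (is.null(attr(d, "frame_interval")))
    attr(d, "frame_interval") <- config$frame_interval
  g <- group_max_project(d, config$group_size)
  detect_flashes(g, config)
}

#' Match detected events to ground truth and score detection
#'
#' Greedy bipartite matching: candidate pairs within `max_dist_px`
#' (spatial, Euclidean) and `max_dt_frames` (projected frames) are
#' matched in ascending order of spatial distance, each event and each
#' truth at most once.
#'
#' @param detected detected event data frame (time_s, x_px, y_px)
#' @param truth ground-truth event data frame (time_s, x_px, y_px)
#' @param eff_dt effective (projected) frame interval in s
#' @param max_dist_px spatial matching gate in pixels
#' @param max_dt_frames temporal matching gate in projected frames
#' @return list with `recall`, `precision`, `n_matched`
#' @export
evaluate_detection <- function(detected, truth, eff_dt = 0.3,
                               max_dist_px = 3, max_dt_frames = 1) {
  if (nrow(truth) == 0 || nrow(detected) == 0)
    return(list(recall = ifelse(nrow(truth) == 0, NA_real_, 0),
                precision = ifelse(nrow(detected) == 0, NA_real_, 0),
                n_matched = 0L))
  ft <- floor(truth$time_s / eff_dt)
  fd <- if ("frame" %in% names(detected)) detected$frame
        else floor(detected$time_s / eff_dt)
  pairs <- list()
  for (i in seq_len(nrow(detected))) {
    dts <- abs(fd[i] - ft)
    dd <- sqrt((detected$x_px[i] - truth$x_px)^2 +
               (detected$y_px[i] - truth$y_px)^2)
    ok <- which(dts <= max_dt_frames & dd <= max_dist_px)
    if (length(ok) > 0)
      pairs[[length(pairs) + 1]] <- cbind(i, ok, dd[ok])
  }
  n_matched <- 0L
  if (length(pairs) > 0) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 3]), , drop = FALSE]
    used_d <- logical(nrow(detected)); used_t <- logical(nrow(truth))
    for (k in seq_len(nrow(pm))) {
      i <- pm[k, 1]; j <- pm[k, 2]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE; used_t[j] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  list(recall = n_matched / nrow(truth),
       precision = n_matched / nrow(detected),
       n_matched = n_matched)
}
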