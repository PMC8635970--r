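#' Background-subtracted mean intensity of a cell ROI
#'
#' Mean over the pixels whose centers fall inside the cell polygon,
#' minus the mean over a background polygon, with optional exclusion
#' masks (e.g. thresholded bright primary-cilia signal) removed from
#' the cell pixels.
#'
#' @param image numeric matrix (rows = y, cols = x), intensities in
#'   counts; pixel centers are at 0-based integer coordinates
#' @param roi a `cell_roi` (or bare vertex matrix)
#' @param background_roi polygon vertex matrix for the background box
#' @param exclusion_masks list of polygon vertex matrices to omit
#' @param channel channel label carried into the result
#' @return list with islet_id, cell_id, channel, mean_intensity
#'   (background-subtracted), background, n_pixels
#' @export
cell_mean_intensity <- function(image, roi, background_roi,
                                exclusion_masks = list(),
                                channel = "glu_tubulin") {
  verts <- if (inherits(roi, "cell_roi")) roi$vertices else as.matrix(roi)
  px <- .pixels_in_polygon(image, verts)
  if (length(exclusion_masks) > 0) {
    for (m in exclusion_masks) {
      ex <- .pixels_in_polygon(image, as.matrix(m))
      px <- px[!(px %in% ex)]
    }
  }
  if (length(px) == 0) stop("degenerate ROI: no pixel centers inside")
  bg_px <- .pixels_in_polygon(image, as.matrix(background_roi))
  if (length(bg_px) == 0) stop("degenerate background ROI")
  bg <- mean(image[bg_px])
  list(islet_id = if (inherits(roi, "cell_roi")) roi$islet_id else NA,
       cell_id = if (inherits(roi, "cell_roi")) roi$cell_id else NA,
       channel = channel,
       mean_intensity = mean(image[px]) - bg,
       background = bg, n_pixels = length(px))
}

# linear indices of pixels whose 0-based centers (x = col-1, y = row-1)
# fall inside the polygon; restricted to the polygon's bounding box
.pixels_in_polygon <- function(image, vertices) {
  xr <- range(vertices[, 1]); yr <- range(vertices[, 2])
  cols <- max(1, floor(xr[1]) + 1):min(ncol(image), ceiling(xr[2]) + 1)
  rows <- max(1, floor(yr[1]) + 1):min(nrow(image), ceiling(yr[2]) + 1)
  grid <- expand.grid(row = rows, col = cols)
  inside <- point_in_polygon(cbind(grid$col - 1, grid$row - 1), vertices)
  (grid$col[inside] - 1L) * nrow(image) + grid$row[inside]
}

#' Coefficient of variation
#'
#' CV = 100 * sd / mean. The sample standard deviation (n - 1
#' denominator) is the default; set `sample_sd = FALSE` for the
#' population form.
#'
#' @param values numeric vector (n >= 2)
#' @param sample_sd use the n - 1 denominator
#' @return CV in percent
#' @export
coefficient_of_variation <- function(values, sample_sd = TRUE) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined: zero mean")
  s <- stats::sd(values)
  if (!sample_sd) s <- s * sqrt((length(values) - 1) / length(values))
  100 * s / m
}

#' Split cells at the islet-average intensity
#'
#' Normalizes each cell's intensity to its islet mean and partitions
#' cells into below-average (< 1) and above-average (>= 1; boundary
#' cells at exactly 1 go to "above") groups, carrying any per-cell
#' metric columns through for rank-based comparison.
#'
#' @param cells data frame with islet_id, intensity, and any metric
#'   columns (e.g. n_events, n_clusters, n_clustered_events)
#' @return `cells` with added norm_intensity and group columns
#' @export
split_by_islet_average <- function(cells) {
  stopifnot(all(c("islet_id", "intensity") %in% names(cells)))
  out <- lapply(split(cells, cells$islet_id), function(s) {
    m <- mean(s$intensity)
    if (m == 0) stop("islet mean intensity is zero")
    s$norm_intensity <- s$intensity / m
    s$group <- ifelse(s$norm_intensity >= 1, "above", "below")
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Calcium-trace statistics
#'
#' Normalizes a per-cell dye trace to its value at the stimulation
#' frame (fold change), then reports the peak amplitude of the
#' post-stimulation fluctuation (max - min of the fold trace) and the
#' summed fold increase over the first minute after stimulation.
#'
#' @param trace intensity per frame
#' @param stim_frame 1-based index of the stimulation frame
#' @param frame_interval seconds per frame
#' @return list with fold_trace, peak_amplitude, first_minute_increase
#' @export
ca_trace_stats <- function(trace, stim_frame, frame_interval) {
  if (stim_frame < 1 || stim_frame > length(trace))
    stop("stim_frame outside the trace")
  if (trace[stim_frame] <= 0)
    stop("cannot normalize: zero intensity at stimulation")
  fold <- trace / trace[stim_frame]
  post <- fold[stim_frame:length(fold)]
  minute <- which(seq_along(trace) > stim_frame &
                  (seq_along(trace) - stim_frame) * frame_interval <= 60)
  list(fold_trace = fold,
       peak_amplitude = max(post) - min(post),
       first_minute_increase = sum(fold[minute] - 1))
}
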