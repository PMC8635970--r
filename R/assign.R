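#' Assign detected events to beta-cell ROIs
#'
#' Each event falling inside exactly one ROI receives that ROI's
#' cell_id; events inside no beta-cell ROI are discarded and counted,
#' mirroring the original analysis in which events outside all outlined
#' beta-cells were dropped. Points exactly on a polygon edge count as
#' inside (closed-boundary convention). An event inside several
#' overlapping ROIs is assigned to the ROI whose centroid is nearest,
#' with a warning.
#'
#' When the events carry an islet_id, each event is only tested against
#' the ROIs of its own islet (different islets are separate recordings
#' that merely share pixel coordinates).
#'
#' @param events event data frame (needs x_px, y_px; other columns are
#'   carried through)
#' @param rois list of `cell_roi` (or an `islet_geometry`)
#' @return list with `events` (assigned events, cell_id and islet_id
#'   filled in) and `n_discarded`
#' @export
assign_events <- function(events, rois) {
  if (inherits(rois, "islet_geometry")) rois <- rois$cells
  rois <- Filter(function(r) isTRUE(r$is_beta), rois)
  if (length(rois) == 0) stop("no beta-cell ROIs supplied")
  n <- nrow(events)
  if (n == 0)
    return(list(events = events, n_discarded = 0L))
  pts <- cbind(events$x_px, events$y_px)
  inside <- vapply(rois, function(r) point_in_polygon(pts, r$vertices),
                   logical(n))
  inside <- matrix(inside, nrow = n)
  if ("islet_id" %in% names(events) && !all(is.na(events$islet_id))) {
    roi_islet <- vapply(rois, `[[`, "", "islet_id")
    same <- outer(events$islet_id, roi_islet, `==`)
    same[is.na(same)] <- TRUE # unassigned events may match any islet
    inside <- inside & same
  }
  hits <- rowSums(inside)
  cell_id <- rep(NA_character_, n)
  islet_id <- rep(NA_character_, n)
  single <- which(hits == 1)
  if (length(single) > 0) {
    j <- apply(inside[single, , drop = FALSE], 1, which.max)
    cell_id[single] <- vapply(rois[j], `[[`, "", "cell_id")
    islet_id[single] <- vapply(rois[j], `[[`, "", "islet_id")
  }
  multi <- which(hits > 1)
  if (length(multi) > 0) {
    warning(length(multi), " event(s) inside overlapping ROIs; ",
            "assigned to the nearest-centroid ROI")
    centroids <- t(vapply(rois, function(r) polygon_centroid(r$vertices),
                          numeric(2)))
    for (i in multi) {
      cand <- which(inside[i, ])
      d2 <- (centroids[cand, 1] - pts[i, 1])^2 +
            (centroids[cand, 2] - pts[i, 2])^2
      j <- cand[which.min(d2)]
      cell_id[i] <- rois[[j]]$cell_id
      islet_id[i] <- rois[[j]]$islet_id
    }
  }
  keep <- hits >= 1
  out <- events[keep, , drop = FALSE]
  out$cell_id <- cell_id[keep]
  out$islet_id <- islet_id[keep]
  rownames(out) <- NULL
  for (a in c("duration", "pixel_size", "field_size", "condition"))
    attr(out, a) <- attr(events, a)
  list(events = out, n_discarded = sum(!keep))
}
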