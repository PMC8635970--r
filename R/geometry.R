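#' Generate an in-silico islet geometry
#'
#' Builds a disk-shaped islet footprint tiled into `n_cells` simple
#' polygons by a bounded Voronoi tessellation of random seed points
#' (each Voronoi cell is obtained by half-plane clipping of the disk).
#' The disk radius is chosen so that the mean cell footprint matches
#' `target_cell_area` (in square micrometres), capped so that the islet
#' stays inside the imaging field.
#'
#' @param n_cells number of cells (>= 1)
#' @param field_size imaging field in pixels, c(width, height)
#' @param pixel_size pixel size in micrometres per pixel
#' @param seed integer seed for reproducibility (NULL = use current RNG)
#' @param target_cell_area mean cell footprint in square micrometres;
#'   the default 120 corresponds to an attached beta-cell footprint
#' @param islet_id identifier attached to the geometry and its cells
#' @param n_disk_vertices number of vertices of the polygonal disk
#' @return an object of class `islet_geometry`: a list with elements
#'   `islet_id`, `cells` (list of `cell_roi`), `pixel_size`, `field_size`
#' @export
generate_islet_geometry <- function(n_cells, field_size = c(256L, 256L),
                                    pixel_size = 0.16, seed = NULL,
                                    target_cell_area = 120,
                                    islet_id = "islet1",
                                    n_disk_vertices = 96L) {
  if (length(n_cells) != 1 || is.na(n_cells) || n_cells < 1)
    stop("n_cells must be a positive integer")
  n_cells <- as.integer(n_cells)
  if (length(field_size) != 2 || any(field_size < 10))
    stop("field_size must be two dimensions of at least 10 px")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (!is.null(seed)) set.seed(seed)

  center <- field_size / 2
  r_target <- sqrt(n_cells * target_cell_area / pixel_size^2 / pi)
  radius <- min(r_target, 0.45 * min(field_size))

  theta <- seq(0, 2 * pi, length.out = n_disk_vertices + 1)[-1]
  disk <- cbind(center[1] + radius * cos(theta),
                center[2] + radius * sin(theta))

  # seed points uniform in the disk (polar method)
  rr <- radius * sqrt(stats::runif(n_cells))
  aa <- stats::runif(n_cells, 0, 2 * pi)
  pts <- cbind(center[1] + rr * cos(aa), center[2] + rr * sin(aa))

  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    poly <- disk
    for (j in seq_len(n_cells)) {
      if (j == i) next
      # keep the side closer to point i: (pj - pi) . x <= (pj - pi).(pi + pj)/2
      a <- pts[j, ] - pts[i, ]
      b <- sum(a * (pts[i, ] + pts[j, ])) / 2
      poly <- .clip_halfplane(poly, a, b)
      if (nrow(poly) < 3) break
    }
    cells[[i]] <- cell_roi(islet_id = islet_id,
                           cell_id = paste0("cell", i),
                           vertices = poly)
  }
  structure(list(islet_id = islet_id, cells = cells,
                 pixel_size = pixel_size, field_size = field_size),
            class = "islet_geometry")
}

#' Construct a cell ROI
#'
#' @param islet_id islet identifier
#' @param cell_id cell identifier
#' @param vertices n x 2 matrix of (x, y) pixel vertices (n >= 3), the
#'   closing edge being implicit
#' @param is_beta logical; non-beta cells are excluded from assignment
#' @param condition optional condition label
#' @return an object of class `cell_roi`
#' @export
cell_roi <- function(islet_id, cell_id, vertices, is_beta = TRUE,
                     condition = NA_character_) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) stop("a cell ROI needs at least 3 vertices")
  colnames(vertices) <- c("x", "y")
  structure(list(islet_id = islet_id, cell_id = cell_id,
                 vertices = vertices, is_beta = isTRUE(is_beta),
                 condition = condition),
            class = "cell_roi")
}

#' @export
print.islet_geometry <- function(x, ...) {
  areas <- vapply(x$cells, function(cl) polygon_area(cl$vertices), 0)
  cat(sprintf("islet_geometry '%s': %d cells, field %d x %d px, %.3g um/px\n",
              x$islet_id, length(x$cells), x$field_size[1], x$field_size[2],
              x$pixel_size))
  cat(sprintf("  mean cell footprint %.1f um^2\n",
              mean(areas) * x$pixel_size^2))
  invisible(x)
}

#' Flatten geometry to a vertex-list data frame
#'
#' @param geometry an `islet_geometry` or list of `cell_roi`
#' @return data frame with columns islet_id, cell_id, vertex_index,
#'   x_px, y_px
#' @export
geometry_to_df <- function(geometry) {
  cells <- if (inherits(geometry, "islet_geometry")) geometry$cells
           else geometry
  do.call(rbind, lapply(cells, function(cl) {
    data.frame(islet_id = cl$islet_id, cell_id = cl$cell_id,
               vertex_index = seq_len(nrow(cl$vertices)),
               x_px = cl$vertices[, 1], y_px = cl$vertices[, 2],
               row.names = NULL)
  }))
}

#' Write cell ROIs to a vertex-list CSV
#' @param geometry an `islet_geometry` or list of `cell_roi`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_rois <- function(geometry, path) {
  utils::write.csv(geometry_to_df(geometry), path, row.names = FALSE)
  invisible(path)
}

#' Read cell ROIs from a vertex-list CSV
#'
#' Expects columns islet_id, cell_id, vertex_index, x_px, y_px. Polygons
#' with fewer than 3 vertices or failing the simplicity check are
#' rejected with an error naming the offending cell.
#'
#' @param path CSV path
#' @return list of `cell_roi`
#' @export
load_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("islet_id", "cell_id", "vertex_index", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("ROI CSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$x_px)) || any(!is.finite(df$y_px)))
    stop("non-numeric vertex coordinate at line(s): ",
         paste(which(!is.finite(df$x_px) | !is.finite(df$y_px)) + 1L,
               collapse = ", "))
  keys <- unique(df[, c("islet_id", "cell_id")])
  rois <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$islet_id == keys$islet_id[i] & df$cell_id == keys$cell_id[i], ]
    sub <- sub[order(sub$vertex_index), ]
    v <- cbind(sub$x_px, sub$y_px)
    if (nrow(v) < 3)
      stop("ROI ", keys$cell_id[i], " in ", keys$islet_id[i],
           " has fewer than 3 vertices")
    if (!polygon_is_simple(v))
      stop("ROI ", keys$cell_id[i], " in ", keys$islet_id[i],
           " is not a simple polygon")
    rois[[i]] <- cell_roi(keys$islet_id[i], keys$cell_id[i], v)
  }
  rois
}
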