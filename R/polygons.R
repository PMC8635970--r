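#' Polygon utilities for cell ROIs
#'
#' Cell outlines are simple closed polygons in pixel coordinates
#' (0-based pixel centers, x rightwards, y downwards). Vertices are
#' stored as an n x 2 matrix with columns x and y; the closing edge
#' from the last vertex back to the first is implicit.
#'
#' @name polygons
#' @keywords internal
NULL

#' Signed area of a polygon (shoelace formula)
#' @param vertices n x 2 matrix of (x, y) vertices
#' @return signed area; positive for counter-clockwise orientation in a
#'   y-up frame (sign is irrelevant for all uses here)
#' @keywords internal
polygon_signed_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  j <- c(seq_len(nrow(vertices))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area
#' @param vertices n x 2 matrix of (x, y) vertices
#' @return area in squared input units
#' @export
polygon_area <- function(vertices) abs(polygon_signed_area(vertices))

#' Polygon centroid
#' @param vertices n x 2 matrix of (x, y) vertices
#' @return length-2 numeric (x, y)
#' @export
polygon_centroid <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  j <- c(seq_len(nrow(vertices))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(vertices))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# orientation of the triplet (p, q, r): >0 counter-clockwise, <0 clockwise,
# 0 collinear (with a scaled tolerance)
.orient <- function(px, py, qx, qy, rx, ry) {
  v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
  scale <- pmax(abs(qx - px) + abs(qy - py), abs(rx - px) + abs(ry - py), 1)
  v[abs(v) < 1e-12 * scale * scale] <- 0
  sign(v)
}

# proper or improper intersection of segments (a1,a2) and (b1,b2)
.segments_intersect <- function(a1, a2, b1, b2) {
  d1 <- .orient(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
  d2 <- .orient(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
  d3 <- .orient(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
  d4 <- .orient(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
  if (d1 != d2 && d3 != d4) return(TRUE)
  on_seg <- function(p, q, r) { # r collinear with pq: is r within the box?
    r[1] <= max(p[1], q[1]) + 1e-12 && r[1] >= min(p[1], q[1]) - 1e-12 &&
    r[2] <= max(p[2], q[2]) + 1e-12 && r[2] >= min(p[2], q[2]) - 1e-12
  }
  (d1 == 0 && on_seg(b1, b2, a1)) || (d2 == 0 && on_seg(b1, b2, a2)) ||
  (d3 == 0 && on_seg(a1, a2, b1)) || (d4 == 0 && on_seg(a1, a2, b2))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Adjacent edges sharing one endpoint are not counted as intersections.
#'
#' @param vertices n x 2 matrix of (x, y) vertices
#' @return logical
#' @export
polygon_is_simple <- function(vertices) {
  n <- nrow(vertices)
  if (n < 3) return(FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      # skip adjacent edges (consecutive, or the first/last pair)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (.segments_intersect(vertices[edges[i, 1], ], vertices[edges[i, 2], ],
                              vertices[edges[j, 1], ], vertices[edges[j, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test (closed boundary)
#'
#' Even-odd (ray crossing) rule with points exactly on an edge or vertex
#' counted as inside, matching the closed-polygon convention used for
#' event-to-cell assignment.
#'
#' @param points n x 2 matrix (or length-2 vector) of query points
#' @param vertices m x 2 polygon vertex matrix
#' @return logical vector of length n
#' @export
point_in_polygon <- function(points, vertices) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  px <- points[, 1]; py <- points[, 2]
  vx <- vertices[, 1]; vy <- vertices[, 2]
  m <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- m
  for (i in seq_len(m)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary: collinear with edge and inside its bounding box
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    scale <- pmax(abs(xj - xi) + abs(yj - yi), 1)
    on_seg <- abs(cross) <= 1e-9 * scale &
      px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
      py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# Sutherland-Hodgman clip of a convex region: keep points with a.x <= b
.clip_halfplane <- function(vertices, a, b) {
  n <- nrow(vertices)
  if (n == 0) return(vertices)
  val <- vertices %*% a - b
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- val[i] <= 0; pj_in <- val[j] <= 0
    if (pi_in) out <- rbind(out, vertices[i, ])
    if (pi_in != pj_in) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, vertices[i, ] + t * (vertices[j, ] - vertices[i, ]))
    }
  }
  out
}

#' Uniform random points inside a polygon (rejection from the bounding box)
#' @param n number of points
#' @param vertices polygon vertex matrix
#' @return n x 2 matrix
#' @keywords internal
sample_in_polygon <- function(n, vertices) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  lo <- apply(vertices, 2, min); hi <- apply(vertices, 2, max)
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  while (filled < n) {
    m <- max(2L * (n - filled), 16L)
    cand <- cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]))
    keep <- cand[point_in_polygon(cand, vertices), , drop = FALSE]
    take <- min(nrow(keep), n - filled)
    if (take > 0) {
      out[(filled + 1):(filled + take), ] <- keep[seq_len(take), ]
      filled <- filled + take
    }
  }
  out
}

#' Gaussian-scattered points truncated to a polygon
#'
#' Draws isotropic Gaussian deviates around `center` and resamples any
#' that fall outside the polygon.
#'
#' @param n number of points
#' @param center length-2 (x, y)
#' @param sigma isotropic standard deviation (same units as vertices)
#' @param vertices polygon vertex matrix
#' @return n x 2 matrix
#' @keywords internal
sample_gaussian_in_polygon <- function(n, center, sigma, vertices) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  tries <- 0L
  while (filled < n && tries < 1000L) {
    m <- max(2L * (n - filled), 16L)
    cand <- cbind(stats::rnorm(m, center[1], sigma),
                  stats::rnorm(m, center[2], sigma))
    keep <- cand[point_in_polygon(cand, vertices), , drop = FALSE]
    take <- min(nrow(keep), n - filled)
    if (take > 0) {
      out[(filled + 1):(filled + take), ] <- keep[seq_len(take), ]
      filled <- filled + take
    }
    tries <- tries + 1L
  }
  if (filled < n) # pathological center/sigma: fall back to the center itself
    out[(filled + 1):n, ] <- matrix(center, n - filled, 2, byrow = TRUE)
  out
}
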