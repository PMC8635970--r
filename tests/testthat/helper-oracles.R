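# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Brute-force DBSCAN: explicit neighborhood graph + breadth-first
# connected components over core points, border points to the
# earliest-time core within eps (same documented tie-break as the
# implementation, independently coded).
dbscan_oracle <- function(coords, eps, min_points, times = NULL) {
  n <- nrow(coords)
  if (is.null(times)) times <- seq_len(n)
  if (n == 0) return(integer(0))
  nb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      nb[i, j] <- sum((coords[i, ] - coords[j, ])^2) <= eps^2
    }
  }
  core <- sapply(seq_len(n), function(i) sum(nb[i, ]) >= min_points)
  comp <- rep(0L, n)
  lab <- 0L
  for (s in order(times, seq_len(n))) {
    if (!core[s] || comp[s] > 0) next
    lab <- lab + 1L
    frontier <- s
    comp[s] <- lab
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(nb[v, ])) {
          if (core[u] && comp[u] == 0L) {
            comp[u] <- lab
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
  }
  out <- comp
  for (i in which(!core)) {
    cand <- which(nb[i, ] & core)
    if (length(cand)) {
      cand <- cand[order(times[cand], cand)]
      out[i] <- comp[cand[1]]
    }
  }
  out
}

# partitions equal up to label renaming (noise label 0 fixed)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0, b == 0)) return(FALSE)
  key_a <- match(a[a != 0], unique(a[a != 0]))
  key_b <- match(b[b != 0], unique(b[b != 0]))
  identical(key_a, key_b)
}

# strict local maxima above a threshold in a matrix (8-neighborhood)
local_maxima <- function(m, threshold) {
  out <- NULL
  for (r in 2:(nrow(m) - 1)) {
    for (cc in 2:(ncol(m) - 1)) {
      v <- m[r, cc]
      if (v <= threshold) next
      nbh <- m[(r - 1):(r + 1), (cc - 1):(cc + 1)]
      if (v == max(nbh) && sum(nbh == v) == 1)
        out <- rbind(out, c(x = cc - 1, y = r - 1, value = v))
    }
  }
  out
}

# pixel-counting area of a disk: number of pixel centers within radius
disk_pixel_area <- function(center, radius, field) {
  g <- expand.grid(x = 0:(field[1] - 1), y = 0:(field[2] - 1))
  sum((g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2)
}

# all-pairs nearest-neighbor distances, one per point
nn_oracle <- function(coords) {
  n <- nrow(coords)
  sapply(seq_len(n), function(i) {
    min(sqrt(colSums((t(coords[-i, , drop = FALSE]) - coords[i, ])^2)))
  })
}
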