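#' Nearest-neighbor distances between within-cell secretion events
#'
#' For every event in a cell with at least two events, the Euclidean
#' distance to its nearest same-cell neighbor, in micrometres. Cells
#' with a single event contribute nothing.
#'
#' @param events assigned event data frame (x_px, y_px, cell_id;
#'   islet_id recommended)
#' @param pixel_size um per px
#' @return numeric vector of distances (one per contributing event)
#' @export
nearest_neighbor_distances <- function(events,
                                       pixel_size = attr(events,
                                                         "pixel_size")) {
  if (is.null(pixel_size)) stop("pixel_size required")
  key <- paste(events$islet_id, events$cell_id, sep = "\r")
  out <- numeric(0)
  for (k in unique(key)) {
    sel <- which(key == k)
    if (length(sel) < 2) next
    d <- as.matrix(stats::dist(cbind(events$x_px[sel], events$y_px[sel])))
    diag(d) <- Inf
    out <- c(out, unname(apply(d, 1, min)) * pixel_size)
  }
  out
}

#' Successive wait times between secretion events
#'
#' Per group (cell, or cluster within cell), event times are sorted
#' ascending and successive differences returned; groups with fewer
#' than two events contribute nothing. Waits from all groups are pooled
#' (rows of the returned frame) to form the time-between-event
#' distribution that is fit to an exponential.
#'
#' @param events event data frame (time_s, cell_id; cluster_id needed
#'   for the cluster groupings)
#' @param grouping "within_cell_all" (all events of a cell),
#'   "within_cell_nonclustered" (cluster_id == 0 only), or
#'   "within_cluster" (each cluster separately)
#' @return data frame with columns islet_id, cell_id, cluster_id
#'   (NA except for within_cluster), cluster_size, wait_s
#' @export
wait_times <- function(events,
                       grouping = c("within_cell_all",
                                    "within_cell_nonclustered",
                                    "within_cluster")) {
  grouping <- match.arg(grouping)
  empty <- data.frame(islet_id = character(0), cell_id = character(0),
                      cluster_id = integer(0), cluster_size = integer(0),
                      wait_s = numeric(0))
  if (nrow(events) == 0) return(empty)
  if (grouping == "within_cell_nonclustered") {
    if (!"cluster_id" %in% names(events))
      stop("cluster_id needed for the non-clustered grouping")
    events <- events[events$cluster_id == 0, , drop = FALSE]
  }
  if (grouping == "within_cluster") {
    if (!"cluster_id" %in% names(events))
      stop("cluster_id needed for the within-cluster grouping")
    events <- events[events$cluster_id > 0, , drop = FALSE]
    key <- paste(events$islet_id, events$cell_id, events$cluster_id,
                 sep = "\r")
  } else {
    key <- paste(events$islet_id, events$cell_id, sep = "\r")
  }
  if (nrow(events) == 0) return(empty)
  rows <- lapply(split(events, key), function(s) {
    if (nrow(s) < 2) return(NULL)
    tt <- sort(s$time_s)
    data.frame(islet_id = s$islet_id[1], cell_id = s$cell_id[1],
               cluster_id = if (grouping == "within_cluster")
                 s$cluster_id[1] else NA_integer_,
               cluster_size = if (grouping == "within_cluster")
                 nrow(s) else NA_integer_,
               wait_s = diff(tt))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Exponential fit of a wait-time sample with KS goodness of fit
#'
#' Maximum-likelihood exponential fit with zero location offset
#' (rate = 1 / mean), followed by a one-sample Kolmogorov-Smirnov test
#' of the sample against Exponential(rate) with the asymptotic p-value,
#' mirroring the original analysis. Note that testing against a rate
#' *estimated from the same sample* makes the asymptotic KS p-value
#' conservative (the Lilliefors effect); `ks_method = "bootstrap"`
#' provides a parametric-bootstrap p-value that corrects this. Supply
#' `rate` to test against a known rate instead.
#'
#' @param waits non-negative wait times in s (n >= 2)
#' @param rate optional known rate; when NULL the MLE is used
#' @param ks_method "asymptotic" or "bootstrap"
#' @param n_boot bootstrap replicates for `ks_method = "bootstrap"`
#' @return object of class `exp_fit`: list with rate, n, ks_stat,
#'   ks_p, sample_mean, ks_method
#' @export
fit_exponential <- function(waits, rate = NULL,
                            ks_method = c("asymptotic", "bootstrap"),
                            n_boot = 500L) {
  ks_method <- match.arg(ks_method)
  waits <- as.numeric(waits)
  if (length(waits) < 2) stop("need at least 2 waits")
  if (any(waits < 0)) stop("waits must be non-negative")
  m <- mean(waits)
  if (m == 0) stop("degenerate fit: all waits are zero")
  estimated <- is.null(rate)
  if (estimated) rate <- 1 / m
  ks <- suppressWarnings(
    stats::ks.test(waits, stats::pexp, rate = rate, exact = FALSE))
  p <- unname(ks$p.value)
  if (ks_method == "bootstrap") {
    n <- length(waits)
    dboot <- vapply(seq_len(n_boot), function(b) {
      x <- stats::rexp(n, rate)
      r <- if (estimated) 1 / mean(x) else rate
      unname(suppressWarnings(
        stats::ks.test(x, stats::pexp, rate = r,
                       exact = FALSE))$statistic)
    }, 0)
    p <- mean(dboot >= unname(ks$statistic))
  }
  structure(list(rate = rate, n = length(waits),
                 ks_stat = unname(ks$statistic), ks_p = p,
                 sample_mean = m, ks_method = ks_method),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "exponential fit: rate %.4g /s (mean wait %.3g s), n = %d\n",
    x$rate, x$sample_mean, x$n))
  cat(sprintf("  KS D = %.4f, p = %.4g (%s)\n", x$ks_stat, x$ks_p,
              x$ks_method))
  invisible(x)
}

#' Pool within-cluster waits by cluster size
#'
#' Waits are pooled across all clusters sharing a size; sizes present
#' in `sizes` but absent from the data map to empty vectors (some
#' conditions lack clusters of a particular size).
#'
#' @param cluster_waits output of `wait_times(..., "within_cluster")`
#' @param sizes integer sizes to report (defaults to the sizes present)
#' @return named list, one numeric vector of waits per size
#' @export
waits_by_cluster_size <- function(cluster_waits, sizes = NULL) {
  if (is.null(sizes)) sizes <- sort(unique(cluster_waits$cluster_size))
  out <- stats::setNames(vector("list", length(sizes)), as.character(sizes))
  for (s in sizes)
    out[[as.character(s)]] <-
      cluster_waits$wait_s[cluster_waits$cluster_size == s]
  out
}

#' Timing histogram of secretion events
#'
#' Counts per half-open 30 s bin [lo, hi), optionally normalized to the
#' percentage of the condition total. Strata: all events, clustered
#' (cluster_id > 0), non-clustered, or the first/last event of each
#' cluster.
#'
#' @param events clustered event data frame (time_s; cluster_id needed
#'   for the non-"all" strata)
#' @param stratum one of "all", "clustered", "nonclustered",
#'   "first_in_cluster", "last_in_cluster"
#' @param bin_width bin width in s (> 0)
#' @param normalize report percentages of the stratum total
#' @param t_max upper edge of the last bin (defaults to covering the
#'   largest time)
#' @return data frame with bin_lo, bin_hi, count and (if `normalize`)
#'   pct; attribute `stratum`
#' @export
timing_histogram <- function(events, stratum = c("all", "clustered",
                                                 "nonclustered",
                                                 "first_in_cluster",
                                                 "last_in_cluster"),
                             bin_width = 30, normalize = FALSE,
                             t_max = NULL) {
  stratum <- match.arg(stratum)
  if (bin_width <= 0) stop("bin_width must be positive")
  tt <- switch(stratum,
    all = events$time_s,
    clustered = events$time_s[events$cluster_id > 0],
    nonclustered = events$time_s[events$cluster_id == 0],
    first_in_cluster = ,
    last_in_cluster = {
      cl <- events[events$cluster_id > 0, , drop = FALSE]
      key <- paste(cl$islet_id, cl$cell_id, cl$cluster_id, sep = "\r")
      agg <- if (stratum == "first_in_cluster") min else max
      as.numeric(vapply(split(cl$time_s, key), agg, 0))
    })
  if (any(tt < 0)) stop("event times must be non-negative")
  if (is.null(t_max)) {
    t_max <- attr(events, "duration")
    if (is.null(t_max)) t_max <- if (length(tt)) max(tt) + 1e-9 else bin_width
  }
  edges <- seq(0, by = bin_width,
               length.out = ceiling(t_max / bin_width) + 1)
  counts <- vapply(seq_len(length(edges) - 1), function(i)
    sum(tt >= edges[i] & tt < edges[i + 1]), 0L)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    count = counts)
  if (normalize)
    out$pct <- if (sum(counts) > 0) 100 * counts / sum(counts) else 0
  attr(out, "stratum") <- stratum
  out
}

#' Cluster lifetimes: first and last event of each hot spot
#'
#' Scatter-ready (first_time, last_time) pairs with derived flags:
#' whether the cluster started in the first secretion phase and
#' whether it was still active within one histogram bin of the
#' recording end.
#'
#' @param clusters output of [cluster_records()]
#' @param phase_boundary end of the first phase in s
#' @param recording_end recording length in s (NA flags if missing)
#' @param bin_width histogram bin width in s, used by `active_at_end`
#' @return `clusters` with initiated_in_first_phase and active_at_end
#'   columns
#' @export
cluster_lifetimes <- function(clusters, phase_boundary = 300,
                              recording_end = NULL, bin_width = 30) {
  clusters$initiated_in_first_phase <- clusters$first_time < phase_boundary
  clusters$active_at_end <- if (is.null(recording_end)) NA else
    clusters$last_time >= recording_end - bin_width
  clusters
}
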