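test_that("three events within the search radius form one cluster", {
  xy <- rbind(c(0, 0), c(5, 0), c(2, 4)) # mutual distances <= 9 px
  lab <- cluster_cell_events(xy)
  expect_equal(lab, c(1L, 1L, 1L))
})

test_that("a pair below the minimum neighborhood stays noise", {
  xy <- rbind(c(0, 0), c(1, 0))
  expect_equal(cluster_cell_events(xy), c(0L, 0L))
  expect_equal(cluster_cell_events(matrix(numeric(0), ncol = 2)),
               integer(0))
  expect_equal(cluster_cell_events(rbind(c(1, 1))), 0L)
})

test_that("clustering matches the brute-force density-scan oracle", {
  set.seed(15)
  params <- cluster_params()
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    xy <- cbind(stats::runif(n, 0, 60), stats::runif(n, 0, 60))
    tt <- stats::runif(n, 0, 600)
    got <- cluster_cell_events(xy, times = tt, params = params)
    want <- dbscan_oracle(xy, params$eps, params$min_points, times = tt)
    expect_true(same_partition(got, want))
  }
})

test_that("cluster membership is independent of input order", {
  set.seed(16)
  xy <- cbind(stats::runif(40, 0, 50), stats::runif(40, 0, 50))
  tt <- stats::runif(40, 0, 600)
  lab <- cluster_cell_events(xy, times = tt)
  perm <- sample(40)
  lab_perm <- cluster_cell_events(xy[perm, ], times = tt[perm])
  # undo the permutation and compare partitions
  undo <- integer(40); undo[perm] <- seq_len(40)
  expect_true(same_partition(lab, lab_perm[undo]))
})

test_that("clustering is invariant under rigid translation", {
  set.seed(17)
  xy <- cbind(stats::runif(30, 0, 40), stats::runif(30, 0, 40))
  l1 <- cluster_cell_events(xy)
  l2 <- cluster_cell_events(sweep(xy, 2, c(123.4, -56.7), `+`))
  expect_identical(l1, l2)
})

test_that("every cluster has at least min_points members", {
  set.seed(18)
  for (rep in 1:10) {
    xy <- cbind(stats::runif(50, 0, 45), stats::runif(50, 0, 45))
    lab <- cluster_cell_events(xy)
    if (any(lab > 0))
      expect_gte(min(table(lab[lab > 0])), 3)
  }
})

test_that("well-separated simulated hot spots are recovered exactly", {
  # hot-spot centers >= 2 * eps apart; sigma 0.3 um keeps events within eps
  p <- preset_with(p_active = 1, scatter_rate = 0,
                   biphasic = flat_profile(),
                   hotspot_count_dist = c(`1` = 1), duration = 5000)
  g <- one_cell_geometry(c(512L, 512L), islet_id = "i1")
  recovered <- 0L; expected <- 0L
  for (s in 1:12) {
    ev <- generate_event_stream(g, p, seed = 400 + s)
    if (nrow(ev) == 0) next
    lab <- cluster_cell_events(cbind(ev$x_px, ev$y_px),
                               times = ev$time_s)
    truth_sizes <- table(ev$true_source)
    expected <- expected + sum(truth_sizes >= 3)
    recovered <- recovered + length(unique(lab[lab > 0]))
  }
  expect_equal(recovered, expected)
})

test_that("micrometre-space clustering scales with pixel size", {
  # equilateral triangle, side 9.2 px: beyond 9 px, within 1.5 um
  xy <- rbind(c(0, 0), c(9.2, 0), c(4.6, 9.2 * sqrt(3) / 2))
  ev <- data.frame(time_s = 1:3, x_px = xy[, 1], y_px = xy[, 2],
                   islet_id = "i", cell_id = "c")
  px_lab <- cluster_events(ev, cluster_params(), pixel_size = 0.16)
  um_lab <- cluster_events(ev, cluster_params(eps = 1.5,
                                              distance_space = "um"),
                           pixel_size = 0.16)
  expect_equal(px_lab$cluster_id, c(0L, 0L, 0L))
  expect_equal(um_lab$cluster_id, c(1L, 1L, 1L))
})

test_that("cell summaries count events, clusters and leftovers", {
  ev <- toy_clustered_events()
  rois <- list(square_roi(0, 0, 120, cell_id = "c1"),
               square_roi(0, 0, 120, islet_id = "i1", cell_id = "c2"))
  cs <- summarize_cells(ev, rois)
  expect_equal(nrow(cs), 2)
  c1 <- cs[cs$cell_id == "c1", ]
  expect_equal(c1$n_events, 8)
  expect_equal(c1$n_clusters, 2)
  expect_equal(c1$n_clustered_events, 6)
  expect_equal(c1$n_nonclustered_events, 2)
  # silent cell present as an all-zero row
  c2 <- cs[cs$cell_id == "c2", ]
  expect_equal(unname(unlist(c2[c("n_events", "n_clusters",
                                  "n_clustered_events",
                                  "n_nonclustered_events")])),
               c(0, 0, 0, 0))
  expect_equal(sum(cs$n_events), nrow(ev))
  expect_equal(cs$n_clustered_events + cs$n_nonclustered_events,
               cs$n_events)
})

test_that("cluster records carry sizes and first/last times", {
  recs <- cluster_records(toy_clustered_events())
  expect_equal(nrow(recs), 2)
  expect_equal(recs$size, c(3L, 3L))
  expect_equal(recs$first_time, c(10, 100))
  expect_equal(recs$last_time, c(15, 150))
})

test_that("islet summaries compute the field-of-view percentages", {
  cs <- data.frame(islet_id = "i1", cell_id = paste0("c", 1:10),
                   n_events = c(2, 1, 3, 5, rep(0, 6)),
                   n_clusters = c(1, 0, 0, 0, rep(0, 6)),
                   n_clustered_events = c(3, rep(0, 9)),
                   n_nonclustered_events = c(-1, 1, 3, 5, rep(0, 6)))
  is <- summarize_islets(cs)
  expect_equal(is$pct_cells_with_event, 40)
  expect_equal(is$pct_cells_with_cluster, 10)
  expect_equal(is$pct_secreting_cells_with_cluster, 25)

  silent <- data.frame(islet_id = "i2", cell_id = paste0("c", 1:5),
                       n_events = 0, n_clusters = 0,
                       n_clustered_events = 0, n_nonclustered_events = 0)
  is2 <- summarize_islets(silent)
  expect_equal(is2$pct_cells_with_event, 0)
  expect_true(is.na(is2$pct_secreting_cells_with_cluster))
})
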