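test_that("nearest-neighbor distances match hand geometry", {
  # two events 1 um apart are mutual nearest neighbors
  ev <- data.frame(time_s = 1:2, x_px = c(0, 1 / 0.16), y_px = 0,
                   islet_id = "i", cell_id = "c")
  expect_equal(nearest_neighbor_distances(ev, 0.16), c(1, 1))

  # collinear events at 0, 1, 3 um
  ev3 <- data.frame(time_s = 1:3, x_px = c(0, 1, 3) / 0.16, y_px = 0,
                    islet_id = "i", cell_id = "c")
  expect_equal(nearest_neighbor_distances(ev3, 0.16), c(1, 1, 2))

  # single-event cells contribute nothing
  ev1 <- data.frame(time_s = 1, x_px = 0, y_px = 0,
                    islet_id = "i", cell_id = "c")
  expect_length(nearest_neighbor_distances(ev1, 0.16), 0)
})

test_that("nearest-neighbor distances match the all-pairs oracle", {
  set.seed(19)
  xy <- cbind(stats::runif(200, 0, 100), stats::runif(200, 0, 100))
  ev <- data.frame(time_s = seq_len(200), x_px = xy[, 1], y_px = xy[, 2],
                   islet_id = "i", cell_id = "c")
  expect_equal(nearest_neighbor_distances(ev, 0.16),
               nn_oracle(xy) * 0.16)
})

test_that("wait times are successive sorted differences per group", {
  ev <- data.frame(time_s = c(15, 10, 12), x_px = 0, y_px = 0,
                   islet_id = "i", cell_id = "c", cluster_id = 1L)
  w <- wait_times(ev, "within_cluster")
  expect_equal(w$wait_s, c(2, 3))
  expect_equal(w$cluster_size, c(3L, 3L))

  one <- data.frame(time_s = 5, x_px = 0, y_px = 0,
                    islet_id = "i", cell_id = "c", cluster_id = 0L)
  expect_equal(nrow(wait_times(one, "within_cell_all")), 0)
})

test_that("pooled wait count equals the sum of group sizes minus one", {
  ev <- toy_clustered_events()
  w_all <- wait_times(ev, "within_cell_all")
  expect_equal(nrow(w_all), nrow(ev) - 1) # one cell
  w_clu <- wait_times(ev, "within_cluster")
  sizes <- table(ev$cluster_id[ev$cluster_id > 0])
  expect_equal(nrow(w_clu), sum(sizes - 1))
  w_non <- wait_times(ev, "within_cell_nonclustered")
  expect_equal(nrow(w_non), sum(ev$cluster_id == 0) - 1)
})

test_that("Poisson event streams pass the exponential KS gate", {
  set.seed(20)
  pass <- vapply(1:100, function(r) {
    waits <- diff(sort(stats::runif(80, 0, 600))) # Poisson stream waits
    fit_exponential(waits)$ks_p > 0.05
  }, TRUE)
  expect_gte(mean(pass), 0.9)
})

test_that("the exponential MLE is rate = 1 / mean", {
  f <- fit_exponential(c(2, 2, 2))
  expect_equal(f$rate, 0.5)
  expect_equal(f$sample_mean, 2)

  set.seed(21)
  f2 <- fit_exponential(stats::rexp(1e4, 1))
  expect_gte(f2$rate, 0.98)
  expect_lte(f2$rate, 1.02)

  expect_error(fit_exponential(c(0, 0, 0)), "degenerate")
  expect_error(fit_exponential(c(1, -1)), "non-negative")
  expect_error(fit_exponential(1), "at least 2")
})

test_that("misspecified wait distributions are rejected by the KS test", {
  set.seed(22)
  f <- fit_exponential(stats::runif(1e4))
  expect_lt(f$ks_p, 0.05)
})

test_that("bootstrap KS p-values are calibrated for estimated rates", {
  set.seed(23)
  p_asym <- p_boot <- numeric(40)
  for (r in 1:40) {
    w <- stats::rexp(60, 0.1)
    p_asym[r] <- fit_exponential(w)$ks_p
    p_boot[r] <- fit_exponential(w, ks_method = "bootstrap",
                                 n_boot = 200)$ks_p
  }
  # estimated-rate asymptotic p-values are conservative (Lilliefors
  # effect); the parametric bootstrap removes most of the bias
  expect_gt(mean(p_asym), 0.6)
  expect_lt(mean(p_boot), mean(p_asym))
  expect_equal(mean(p_boot < 0.05), 0.05, tolerance = 0.1)
})

test_that("waits pool by cluster size with empty sizes reported", {
  cw <- data.frame(islet_id = "i", cell_id = "c",
                   cluster_id = c(1, 1, 2, 2),
                   cluster_size = 3L, wait_s = c(1, 2, 4, 5))
  by_size <- waits_by_cluster_size(cw, sizes = c(3, 6))
  expect_equal(by_size[["3"]], c(1, 2, 4, 5))
  expect_length(by_size[["6"]], 0)
})

test_that("per-size mean waits shorten as simulated clusters grow", {
  wbs <- simulate_size_waits(6000, alpha = 0.05, beta = 0.02,
                             sizes = 3:8, seed = 24)
  means <- vapply(wbs, mean, 0)
  sizes <- as.numeric(names(means))
  expect_lt(stats::cor(sizes, means, method = "spearman"), 0)
  expect_equal(means[["3"]], 1 / 0.11, tolerance = 0.15)
  expect_equal(means[["8"]], 1 / 0.21, tolerance = 0.15)
})

test_that("timing histograms use half-open 30 s bins", {
  ev <- data.frame(time_s = 65, x_px = 0, y_px = 0,
                   islet_id = "i", cell_id = "c", cluster_id = 0L)
  h <- timing_histogram(ev, "all", t_max = 120)
  expect_equal(h$count[h$bin_lo == 60 & h$bin_hi == 90], 1)
  expect_equal(sum(h$count), 1)
  expect_error(timing_histogram(ev, "all", bin_width = 0), "positive")
})

test_that("first/last-in-cluster histograms pick the cluster extremes", {
  ev <- data.frame(time_s = c(100, 130, 150), x_px = c(0, 0.5, 1),
                   y_px = 0, islet_id = "i", cell_id = "c",
                   cluster_id = 1L)
  hf <- timing_histogram(ev, "first_in_cluster", t_max = 300)
  hl <- timing_histogram(ev, "last_in_cluster", t_max = 300)
  expect_equal(hf$count[hf$bin_lo == 90], 1)
  expect_equal(sum(hf$count), 1)
  expect_equal(hl$count[hl$bin_lo == 150], 1) # 150 s: half-open [150, 180)
})

test_that("normalized histograms sum to 100 percent and ignore order", {
  set.seed(25)
  ev <- data.frame(time_s = stats::runif(300, 0, 600), x_px = 0, y_px = 0,
                   islet_id = "i", cell_id = "c", cluster_id = 0L)
  h1 <- timing_histogram(ev, "all", normalize = TRUE, t_max = 600)
  expect_equal(sum(h1$pct), 100, tolerance = 0.01)
  h2 <- timing_histogram(ev[sample(300), ], "all", normalize = TRUE,
                         t_max = 600)
  expect_equal(h1$count, h2$count)
})

test_that("cluster lifetimes flag first-phase starts and late activity", {
  recs <- data.frame(islet_id = "i", cell_id = "c", cluster_id = 1:2,
                     size = 3L, first_time = c(100, 400),
                     last_time = c(150, 590))
  lt <- cluster_lifetimes(recs, phase_boundary = 300, recording_end = 600)
  expect_equal(lt$initiated_in_first_phase, c(TRUE, FALSE))
  expect_equal(lt$active_at_end, c(FALSE, TRUE))
})

test_that("truncated cluster processes end mostly in the first phase", {
  # hot spots emitting only before the phase boundary: last events sit
  # below 300 s even after detection-free clustering
  p <- preset_with(p_active = 1, scatter_rate = 0,
                   biphasic = flat_profile(),
                   hotspot_count_dist = c(`1` = 1), duration = 300)
  g <- one_cell_geometry(c(256L, 256L))
  last_times <- unlist(lapply(1:15, function(s) {
    ev <- generate_event_stream(g, p, seed = 500 + s)
    ev <- cluster_events(ev, cluster_params())
    cluster_records(ev)$last_time
  }))
  expect_gt(length(last_times), 5)
  expect_gte(mean(last_times < 300), 0.5)
})
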