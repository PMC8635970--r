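test_that("single-cell tessellation is the whole clipped disk", {
  g <- generate_islet_geometry(1, c(256L, 256L), 0.16, seed = 7)
  expect_length(g$cells, 1)
  v <- g$cells[[1]]$vertices
  expect_gt(polygon_area(v), 0)
  expect_true(all(v[, 1] >= 0 & v[, 1] <= 256 & v[, 2] >= 0 & v[, 2] <= 256))
  # the single Voronoi cell is the uncut disk: area matches the
  # pixel-counting oracle on the rasterized disk
  r <- sqrt(120 / 0.16^2 / pi)
  oracle <- disk_pixel_area(c(128, 128), r, c(256L, 256L))
  expect_lt(abs(polygon_area(v) - oracle) / oracle, 0.02)
})

test_that("tessellation cell areas sum to the disk area", {
  g <- generate_islet_geometry(20, c(512L, 512L), 0.16, seed = 1)
  expect_length(g$cells, 20)
  areas <- vapply(g$cells, function(cl) polygon_area(cl$vertices), 0)
  r <- sqrt(20 * 120 / 0.16^2 / pi)
  oracle <- disk_pixel_area(c(256, 256), r, c(512L, 512L))
  expect_lt(abs(sum(areas) - oracle) / oracle, 0.02)
  for (cl in g$cells) expect_true(polygon_is_simple(cl$vertices))
})

test_that("geometry generation is deterministic and validates input", {
  g1 <- generate_islet_geometry(8, c(256L, 256L), 0.16, seed = 1)
  g2 <- generate_islet_geometry(8, c(256L, 256L), 0.16, seed = 1)
  expect_identical(lapply(g1$cells, `[[`, "vertices"),
                   lapply(g2$cells, `[[`, "vertices"))
  expect_error(generate_islet_geometry(0, c(256L, 256L), 0.16),
               "positive integer")
  expect_error(generate_islet_geometry(5, c(8L, 256L), 0.16), "10 px")
})

test_that("no cells are activated when p_active is zero", {
  g <- one_cell_geometry()
  ev <- generate_event_stream(g, preset_with(p_active = 0), seed = 1)
  expect_equal(nrow(ev), 0)
})

test_that("fraction of active cells matches the activation probability", {
  # scatter-only preset so activation is read off events directly
  p <- preset_with(p_active = 0.42, hotspot_count_dist = c(`0` = 1),
                   scatter_rate = 0.05, biphasic = flat_profile())
  g <- generate_islet_geometry(125, c(1024L, 1024L), 0.16, seed = 11)
  frac_active <- vapply(1:4, function(s) {
    ev <- generate_event_stream(g, p, seed = 100 + s)
    length(unique(ev$cell_id)) / 125
  }, 0)
  se <- sqrt(0.42 * 0.58 / 500)
  expect_lt(abs(mean(frac_active) - 0.42), 3 * se)
})

test_that("hot-spot waits are exponential with the preset rate", {
  # alpha = 0.05, beta = 0, flat profile (no thinning): mean wait 20 s
  p <- preset_with(p_active = 1, alpha = 0.05, beta = 0,
                   scatter_rate = 0, biphasic = flat_profile(),
                   hotspot_count_dist = c(`1` = 1),
                   size_dist = c(`60` = 1), duration = 1e5)
  g <- one_cell_geometry()
  waits <- unlist(lapply(1:18, function(s) {
    ev <- generate_event_stream(g, p, seed = s)
    diff(sort(ev$time_s))
  }))
  expect_gt(length(waits), 1000)
  waits <- waits[seq_len(1000)]
  expect_lt(abs(mean(waits) - 20), 2 * 20 / sqrt(1000))
})

test_that("event positions fall inside their assigned cell polygon", {
  g <- generate_islet_geometry(12, c(512L, 512L), 0.16, seed = 3)
  ev <- generate_event_stream(g, condition_preset("noc_high"), seed = 4)
  expect_gt(nrow(ev), 0)
  for (cl in g$cells) {
    sel <- ev$cell_id == cl$cell_id
    if (!any(sel)) next
    expect_true(all(point_in_polygon(cbind(ev$x_px[sel], ev$y_px[sel]),
                                     cl$vertices)))
  }
})

test_that("event streams are deterministic given the seed", {
  g <- generate_islet_geometry(6, c(256L, 256L), 0.16, seed = 5)
  e1 <- generate_event_stream(g, condition_preset("control_high"), seed = 9)
  e2 <- generate_event_stream(g, condition_preset("control_high"), seed = 9)
  expect_identical(e1, e2)
})

test_that("mean within-spot wait decreases with hot-spot size", {
  p <- preset_with(p_active = 1, scatter_rate = 0,
                   biphasic = flat_profile(),
                   hotspot_count_dist = c(`1` = 1), duration = 1e4)
  g <- one_cell_geometry()
  stats_by_size <- do.call(rbind, lapply(1:60, function(s) {
    size <- 3 + (s %% 6)
    p$size_dist <- stats::setNames(1, size)
    ev <- generate_event_stream(g, p, seed = 200 + s)
    if (nrow(ev) < 2) return(NULL)
    data.frame(size = size, mean_wait = mean(diff(sort(ev$time_s))))
  }))
  m <- tapply(stats_by_size$mean_wait, stats_by_size$size, mean)
  # monotone decreasing trend across sizes 3..8
  expect_lt(stats::cor(as.numeric(names(m)), m, method = "spearman"), 0)
  expect_gt(m["3"], m["8"])
})

test_that("high-glucose time marginal is bimodal at the configured peaks", {
  p <- preset_with(p_active = 1, hotspot_count_dist = c(`0` = 1),
                   scatter_rate = 1)
  g <- generate_islet_geometry(25, c(512L, 512L), 0.16, seed = 21)
  tt <- unlist(lapply(1:3, function(s)
    generate_event_stream(g, p, seed = 300 + s)$time_s))
  expect_gt(length(tt), 1e4)
  d <- stats::density(tt, bw = 15, from = 0, to = 600)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  peaks <- peaks[order(d$y[peaks], decreasing = TRUE)][1:2]
  pt <- sort(d$x[peaks])
  expect_lt(abs(pt[1] - 180), 30)
  expect_lt(abs(pt[2] - 570), 30)
})

test_that("noise-only movies have the configured background and noise", {
  g <- one_cell_geometry(c(64L, 64L))
  ev <- data.frame(time_s = numeric(0), x_px = numeric(0),
                   y_px = numeric(0))
  attr(ev, "duration") <- 3
  mv <- render_movie(ev, g, render_params(background_level = 100,
                                          noise_sigma = 20), seed = 1)
  expect_equal(dim(mv)[3], ceiling(3 / 0.06))
  expect_lt(abs(mean(mv) - 100), 0.5)
  expect_lt(abs(stats::sd(mv) - 20), 0.5)
})

test_that("a rendered flash peaks at the event position", {
  g <- one_cell_geometry(c(128L, 128L))
  ev <- data.frame(time_s = 1.0, x_px = 50, y_px = 60)
  attr(ev, "duration") <- 3
  mv <- render_movie(ev, g, render_params(), seed = 2)
  d <- difference_stack(mv)
  idx <- arrayInd(which.max(d), dim(d))
  expect_equal(idx[3], floor(1.0 / 0.06)) # difference frame at onset
  expect_lt(abs((idx[2] - 1) - 50), 1.5)
  expect_lt(abs((idx[1] - 1) - 60), 1.5)
})

test_that("two nearby flashes render as two separated local maxima", {
  g <- one_cell_geometry(c(128L, 128L))
  ev <- data.frame(time_s = c(1.0, 1.0), x_px = c(50, 70), y_px = c(60, 60))
  attr(ev, "duration") <- 3
  mv <- render_movie(ev, g, render_params(noise_sigma = 5), seed = 3)
  frame <- mv[, , floor(1.0 / 0.06) + 1]
  lm <- local_maxima(frame, 4000)
  expect_gte(nrow(lm), 2)
  top2 <- lm[order(lm[, "value"], decreasing = TRUE)[1:2], ]
  expect_gte(sqrt(sum((top2[1, 1:2] - top2[2, 1:2])^2)), 15)
})

test_that("rendering rejects out-of-field and out-of-time events", {
  g <- one_cell_geometry(c(64L, 64L))
  bad <- data.frame(time_s = 1, x_px = 200, y_px = 10)
  attr(bad, "duration") <- 3
  expect_error(render_movie(bad, g), "outside the field")
  late <- data.frame(time_s = 10, x_px = 10, y_px = 10)
  attr(late, "duration") <- 3
  expect_error(render_movie(late, g), "outside")
})

test_that("movies survive a TIFF round trip", {
  g <- one_cell_geometry(c(64L, 64L))
  ev <- data.frame(time_s = 0.5, x_px = 30, y_px = 30)
  attr(ev, "duration") <- 1.5
  mv <- render_movie(ev, g, render_params(noise_sigma = 10), seed = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(mv, path)
  back <- read_movie(path)
  expect_equal(dim(back), dim(mv))
  expect_lt(max(abs(back - mv)), 1.01) # 16-bit quantization over 0..65535
})
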