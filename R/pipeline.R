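#' Run the full hot-spot analysis pipeline
#'
#' Executes the staged workflow — input (simulate, detect from a movie,
#' or load an event table), event-to-cell assignment, hot-spot
#' clustering, chance-cluster null, wait-time kinetics, size-rate
#' model, report — writing each stage's CSV outputs plus a JSON
#' manifest recording seeds, parameters and row counts. Re-running
#' with the same config reproduces all outputs.
#'
#' @param config a list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{mode}{"synthetic", "movie", or "event_table"}
#'     \item{out_dir}{output directory (created if needed)}
#'     \item{seed}{integer master seed}
#'     \item{preset}{condition name, synthetic mode}
#'     \item{n_islets, n_cells}{synthetic study size}
#'     \item{movie, rois}{paths, movie mode}
#'     \item{events, rois}{paths, event_table mode}
#'     \item{eps, min_points}{clustering parameters}
#'     \item{null_replicates}{chance-null replicates (default 200)}
#'     \item{rate_model}{logical; fit the size-rate model if enough data}
#'   }
#' @return the manifest, invisibly (a list; also written as
#'   manifest.json in `out_dir`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(mode = "synthetic", out_dir = "pipeline_out", seed = 1L,
                   preset = "control_high", n_islets = 3L, n_cells = 20L,
                   eps = 9, min_points = 3L, null_replicates = 200L,
                   rate_model = TRUE)
  config <- utils::modifyList(defaults, config)
  if (!config$mode %in% c("synthetic", "movie", "event_table"))
    stop("mode must be one of synthetic, movie, event_table")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, mode = config$mode,
                   parameters = config[setdiff(names(config), "out_dir")],
                   stages = list())
  out <- function(name) file.path(config$out_dir, name)
  add_stage <- function(name, files, counts) {
    manifest$stages[[name]] <<- list(outputs = files, rows = counts)
  }

  # stage 1: input
  if (config$mode == "synthetic") {
    study <- simulate_study(config$preset, n_islets = config$n_islets,
                            n_cells = config$n_cells, seed = config$seed)
    events <- study$events
    rois <- unlist(lapply(study$geometries, `[[`, "cells"),
                   recursive = FALSE)
    write_rois(rois, out("rois.csv"))
  } else if (config$mode == "movie") {
    movie <- read_movie(config$movie)
    events <- detect_events(movie)
    rois <- load_rois(config$rois)
    attr(events, "pixel_size") <- config$pixel_size %||% 0.16
  } else {
    events <- read_events(config$events)
    rois <- load_rois(config$rois)
    attr(events, "pixel_size") <- config$pixel_size %||% 0.16
    if (!is.null(config$duration))
      attr(events, "duration") <- config$duration
  }
  if (config$mode != "synthetic") write_rois(rois, out("rois.csv"))
  write_events(events, out("events.csv"))
  add_stage("input", c("events.csv", "rois.csv"),
            c(events = nrow(events), rois = length(rois)))

  # stage 2: assignment
  asg <- assign_events(events, rois)
  write_events(asg$events, out("assigned.csv"))
  add_stage("assign", "assigned.csv",
            c(assigned = nrow(asg$events), discarded = asg$n_discarded))

  # stage 3: clustering + summaries
  params <- cluster_params(eps = config$eps, min_points = config$min_points)
  clustered <- cluster_events(asg$events, params)
  clusters <- cluster_records(clustered)
  cells <- summarize_cells(clustered, rois)
  islets <- summarize_islets(cells)
  write_events(clustered, out("clustered.csv"))
  utils::write.csv(clusters, out("clusters.csv"), row.names = FALSE)
  utils::write.csv(cells, out("cell_summary.csv"), row.names = FALSE)
  utils::write.csv(islets, out("islet_summary.csv"), row.names = FALSE)
  add_stage("cluster", c("clustered.csv", "clusters.csv",
                         "cell_summary.csv", "islet_summary.csv"),
            c(clustered_events = sum(clustered$cluster_id > 0),
              clusters = nrow(clusters), cells = nrow(cells),
              islets = nrow(islets)))

  # stage 4: chance-cluster null on the typical cell footprint
  nmax <- max(cells$n_events, 2L)
  null_res <- simulate_chance_clusters(
    chance_cell_disk(), n_events_grid = unique(pmin(c(2, 5, 10, nmax), 40)),
    k_grid = 2:4, replicates = max(config$null_replicates, 100L),
    seed = config$seed + 7777L)
  utils::write.csv(as.data.frame(null_res), out("chance_null.csv"),
                   row.names = FALSE)
  add_stage("chance_null", "chance_null.csv", c(rows = nrow(null_res)))

  # stage 5: kinetics
  waits_cell <- wait_times(clustered, "within_cell_all")
  waits_non <- wait_times(clustered, "within_cell_nonclustered")
  waits_clu <- wait_times(clustered, "within_cluster")
  tag <- function(df, g) { df$grouping <- rep(g, nrow(df)); df }
  waits_all <- rbind(tag(waits_cell, "within_cell_all"),
                     tag(waits_non, "within_cell_nonclustered"),
                     tag(waits_clu, "within_cluster"))
  utils::write.csv(waits_all, out("waits.csv"), row.names = FALSE)
  fits <- list()
  for (g in unique(waits_all$grouping)) {
    ws <- waits_all$wait_s[waits_all$grouping == g]
    if (length(ws) >= 2 && mean(ws) > 0) {
      f <- fit_exponential(ws)
      fits[[g]] <- data.frame(grouping = g, rate = f$rate, n = f$n,
                              ks_stat = f$ks_stat, ks_p = f$ks_p,
                              sample_mean = f$sample_mean)
    }
  }
  fits <- do.call(rbind, fits)
  utils::write.csv(fits, out("exp_fits.csv"), row.names = FALSE)
  hist_all <- timing_histogram(clustered, "all", normalize = TRUE)
  utils::write.csv(hist_all, out("timing_histogram.csv"), row.names = FALSE)
  add_stage("kinetics", c("waits.csv", "exp_fits.csv",
                          "timing_histogram.csv"),
            c(waits = nrow(waits_all),
              fits = if (is.null(fits)) 0L else nrow(fits)))

  # stage 6: size-rate model
  wbs <- waits_by_cluster_size(waits_clu)
  wbs <- wbs[vapply(wbs, length, 0L) > 0]
  enough <- length(wbs) >= 2 && sum(vapply(wbs, length, 0L)) >= 10
  if (config$rate_model && enough) {
    fit <- fit_size_rate_model(
      wbs, size_rate_spec(draws_per_chain = 1000L,
                          seed = config$seed %% 100000L + 1L))
    post <- data.frame(
      parameter = c("alpha", "beta"),
      mean = c(mean(fit$alpha_samples), mean(fit$beta_samples)),
      hdpi_lo = c(fit$hdpi_alpha[1], fit$hdpi_beta[1]),
      hdpi_hi = c(fit$hdpi_alpha[2], fit$hdpi_beta[2]),
      r_hat = unname(fit$rhat), ess = unname(fit$ess))
    waics <- data.frame(waic_full = fit$waic_full,
                        waic_null = fit$waic_null,
                        delta_waic = fit$delta_waic)
  } else {
    post <- data.frame(parameter = character(0), mean = numeric(0),
                       hdpi_lo = numeric(0), hdpi_hi = numeric(0),
                       r_hat = numeric(0), ess = numeric(0))
    waics <- data.frame(waic_full = NA_real_, waic_null = NA_real_,
                        delta_waic = NA_real_)
  }
  utils::write.csv(post, out("rate_model_posterior.csv"), row.names = FALSE)
  utils::write.csv(waics, out("rate_model_waic.csv"), row.names = FALSE)
  add_stage("rate_model", c("rate_model_posterior.csv",
                            "rate_model_waic.csv"),
            c(parameters = nrow(post)))

  # stage 7: report / conservation checks
  stopifnot(nrow(asg$events) + asg$n_discarded == nrow(events),
            sum(cells$n_clustered_events) + sum(cells$n_nonclustered_events)
              == nrow(asg$events))
  add_stage("report", "manifest.json",
            c(events_in = nrow(events), assigned = nrow(asg$events),
              discarded = asg$n_discarded))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
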