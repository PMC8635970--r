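#' Biphasic glucose-response profile
#'
#' Relative event-rate profile over the recording: a flat baseline plus
#' two Gaussian bumps whose defaults place the first-phase peak in the
#' 2-4 min window and the second-phase peak in the 9-10 min window after
#' glucose stimulation, the known timing of biphasic insulin secretion.
#' Amplitudes are unitless multipliers of the baseline.
#'
#' @param baseline baseline relative rate (events/s multiplier)
#' @param peak1_time,peak1_width,peak1_amp first-phase bump (s, s, x)
#' @param peak2_time,peak2_width,peak2_amp second-phase bump (s, s, x)
#' @return object of class `biphasic_profile`
#' @export
biphasic_profile <- function(baseline = 1, peak1_time = 180, peak1_width = 45,
                             peak1_amp = 2, peak2_time = 570, peak2_width = 30,
                             peak2_amp = 1.5) {
  if (peak1_width <= 0 || peak2_width <= 0) stop("peak widths must be > 0")
  if (peak1_amp < 0 || peak2_amp < 0) stop("peak amplitudes must be >= 0")
  structure(list(baseline = baseline,
                 peak1_time = peak1_time, peak1_width = peak1_width,
                 peak1_amp = peak1_amp,
                 peak2_time = peak2_time, peak2_width = peak2_width,
                 peak2_amp = peak2_amp),
            class = "biphasic_profile")
}

#' Evaluate a biphasic profile
#' @param profile a `biphasic_profile`
#' @param t time(s) in seconds
#' @return relative rate at `t`
#' @export
profile_value <- function(profile, t) {
  profile$baseline * (1 +
    profile$peak1_amp * exp(-(t - profile$peak1_time)^2 /
                              (2 * profile$peak1_width^2)) +
    profile$peak2_amp * exp(-(t - profile$peak2_time)^2 /
                              (2 * profile$peak2_width^2)))
}

# thinning modulation in [0, 1]: profile relative to its maximum
.profile_modulation <- function(profile, t, duration) {
  tg <- seq(0, duration, length.out = 512)
  profile_value(profile, t) / max(profile_value(profile, tg))
}

#' Condition presets for the synthetic-data generator
#'
#' Returns the generator parameters for one experimental condition.
#' Activation probabilities for the high-glucose presets are anchored to
#' the observed fractions of secreting cells: 42% in control, 66% under
#' nocodazole (microtubule depolymerization), 27% under taxol
#' (microtubule hyper-stabilization, similar to low glucose). Nocodazole
#' additionally allows multiple hot spots per active cell, taxol
#' suppresses hot spots. Within-cluster event times follow exponential
#' waits at rate `alpha + beta * size` (events/s); the defaults
#' alpha = 0.05, beta = 0.02 give mean within-cluster waits of 5-10 s
#' for cluster sizes 3-8. KCl presets are short depolarization
#' recordings with a single early peak.
#'
#' @param name one of "control_low", "control_high", "noc_low",
#'   "noc_high", "taxol_low", "taxol_high", "kcl", "kcl_glucose"
#' @return object of class `condition_preset`: a list with fields
#'   `name`, `p_active`, `hotspot_count_dist` (named probability vector
#'   over hot spots per active cell), `size_dist` (named probability
#'   vector over hot-spot target sizes), `scatter_rate` (peak events/s
#'   per cell for non-clustered events), `alpha`, `beta`,
#'   `hotspot_sigma_um`, `biphasic`, `duration` (s)
#' @export
condition_preset <- function(name = c("control_low", "control_high",
                                      "noc_low", "noc_high",
                                      "taxol_low", "taxol_high",
                                      "kcl", "kcl_glucose")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    p_active = 0.42,
    hotspot_count_dist = c(`1` = 0.7, `2` = 0.3),
    size_dist = c(`3` = 0.35, `4` = 0.25, `5` = 0.17, `6` = 0.11,
                  `7` = 0.07, `8` = 0.05),
    scatter_rate = 0.05,
    alpha = 0.05, beta = 0.02,
    hotspot_sigma_um = 0.3,
    biphasic = biphasic_profile(),
    duration = 600
  )
  flat <- biphasic_profile(peak1_amp = 0, peak2_amp = 0)
  kcl_prof <- biphasic_profile(peak1_time = 20, peak1_width = 15,
                               peak1_amp = 4, peak2_amp = 0)
  mod <- switch(name,
    control_high = list(),
    control_low = list(p_active = 0.27, biphasic = flat,
                       hotspot_count_dist = c(`0` = 0.6, `1` = 0.4),
                       scatter_rate = 0.02),
    noc_high = list(p_active = 0.66,
                    hotspot_count_dist = c(`1` = 0.3, `2` = 0.4, `3` = 0.3),
                    biphasic = biphasic_profile(peak1_time = 270,
                                                peak1_width = 120,
                                                peak1_amp = 2,
                                                peak2_amp = 0)),
    noc_low = list(p_active = 0.30, biphasic = flat,
                   hotspot_count_dist = c(`0` = 0.6, `1` = 0.4),
                   scatter_rate = 0.02),
    taxol_high = list(p_active = 0.27,
                      hotspot_count_dist = c(`0` = 0.5, `1` = 0.5)),
    taxol_low = list(p_active = 0.25, biphasic = flat,
                     hotspot_count_dist = c(`0` = 0.6, `1` = 0.4),
                     scatter_rate = 0.02),
    kcl = list(p_active = 0.8, duration = 150, biphasic = kcl_prof,
               hotspot_count_dist = c(`1` = 0.6, `2` = 0.4)),
    kcl_glucose = list(p_active = 0.85, duration = 150, biphasic = kcl_prof,
                       scatter_rate = 0.08,
                       hotspot_count_dist = c(`1` = 0.5, `2` = 0.5))
  )
  preset <- utils::modifyList(base, mod)
  stopifnot(preset$p_active >= 0, preset$p_active <= 1,
            preset$alpha >= 0, preset$beta >= 0, preset$duration > 0)
  class(preset) <- "condition_preset"
  preset
}

# draw one value from a named probability vector (names = integer values)
.sample_named <- function(dist) {
  as.integer(sample(names(dist), 1, prob = dist))
}

# exponential arrivals at `rate`, thinned by the profile modulation,
# stopped after `target` accepted events or at `duration`
.thinned_waits <- function(rate, target, profile, duration) {
  t <- 0; out <- numeric(0)
  if (rate <= 0) return(out)
  while (length(out) < target) {
    t <- t + stats::rexp(1, rate)
    if (t > duration) break
    if (stats::runif(1) < .profile_modulation(profile, t, duration))
      out <- c(out, t)
  }
  out
}

#' Simulate a secretion-event stream for one islet
#'
#' Per cell: Bernoulli(`p_active`) activation; each active cell draws a
#' hot-spot count, each hot spot a center uniform in the cell polygon
#' and a target size from `size_dist`; hot-spot event times are
#' cumulative exponential waits at rate `alpha + beta * size`, thinned
#' by the biphasic profile, and positions are isotropic Gaussian
#' (`hotspot_sigma_um`) around the center truncated to the cell.
#' Scattered (non-clustered) events are a Poisson process at peak rate
#' `scatter_rate`, thinned by the same profile, with positions uniform
#' in the cell. Every event carries its true source label for
#' ground-truth evaluation.
#'
#' @param geometry an `islet_geometry`
#' @param preset a `condition_preset`
#' @param seed integer seed (NULL = use current RNG)
#' @return data frame with columns time_s, x_px, y_px, islet_id,
#'   cell_id, true_source ("scatter" or "hotspot_<cell>_<k>"), ordered
#'   by time; attributes `duration`, `pixel_size`, `field_size`,
#'   `condition`
#' @export
generate_event_stream <- function(geometry, preset, seed = NULL) {
  stopifnot(inherits(geometry, "islet_geometry"),
            inherits(preset, "condition_preset"))
  if (preset$duration <= 0) stop("preset duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  sigma_px <- preset$hotspot_sigma_um / geometry$pixel_size
  rows <- list()
  for (cl in geometry$cells) {
    if (stats::runif(1) >= preset$p_active) next
    n_hs <- .sample_named(preset$hotspot_count_dist)
    if (n_hs > 0) {
      for (h in seq_len(n_hs)) {
        ctr <- sample_in_polygon(1, cl$vertices)[1, ]
        size <- .sample_named(preset$size_dist)
        tt <- .thinned_waits(preset$alpha + preset$beta * size, size,
                             preset$biphasic, preset$duration)
        if (length(tt) == 0) next
        xy <- sample_gaussian_in_polygon(length(tt), ctr, sigma_px,
                                         cl$vertices)
        rows[[length(rows) + 1]] <- data.frame(
          time_s = tt, x_px = xy[, 1], y_px = xy[, 2],
          islet_id = geometry$islet_id, cell_id = cl$cell_id,
          true_source = paste0("hotspot_", cl$cell_id, "_", h))
      }
    }
    ts <- .thinned_waits(preset$scatter_rate, Inf, preset$biphasic,
                         preset$duration)
    if (length(ts) > 0) {
      xy <- sample_in_polygon(length(ts), cl$vertices)
      rows[[length(rows) + 1]] <- data.frame(
        time_s = ts, x_px = xy[, 1], y_px = xy[, 2],
        islet_id = geometry$islet_id, cell_id = cl$cell_id,
        true_source = "scatter")
    }
  }
  ev <- if (length(rows) == 0) {
    data.frame(time_s = numeric(0), x_px = numeric(0), y_px = numeric(0),
               islet_id = character(0), cell_id = character(0),
               true_source = character(0))
  } else {
    do.call(rbind, rows)
  }
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "duration") <- preset$duration
  attr(ev, "pixel_size") <- geometry$pixel_size
  attr(ev, "field_size") <- geometry$field_size
  attr(ev, "condition") <- preset$name
  ev
}

#' Simulate several islets under one condition
#'
#' @param preset a `condition_preset` or preset name
#' @param n_islets number of islets
#' @param n_cells cells per islet
#' @param seed integer seed; islet i uses seed + i for both geometry and
#'   events
#' @param field_size,pixel_size passed to [generate_islet_geometry()]
#' @return list with elements `geometries` (list of `islet_geometry`)
#'   and `events` (one pooled data frame, islets distinguished by
#'   islet_id)
#' @export
simulate_study <- function(preset, n_islets = 16, n_cells = 20, seed = 1,
                           field_size = c(512L, 512L), pixel_size = 0.16) {
  if (is.character(preset)) preset <- condition_preset(preset)
  geoms <- vector("list", n_islets)
  evs <- vector("list", n_islets)
  for (i in seq_len(n_islets)) {
    geoms[[i]] <- generate_islet_geometry(
      n_cells, field_size = field_size, pixel_size = pixel_size,
      seed = seed + i, islet_id = sprintf("islet%02d", i))
    ev <- generate_event_stream(geoms[[i]], preset, seed = 100000L + seed + i)
    evs[[i]] <- ev
  }
  events <- do.call(rbind, evs)
  rownames(events) <- NULL
  attr(events, "duration") <- preset$duration
  attr(events, "pixel_size") <- pixel_size
  attr(events, "condition") <- preset$name
  list(geometries = geoms, events = events)
}

#' Rendering parameters for synthetic TIRF movies
#'
#' @param psf_sigma Gaussian spot sigma in pixels
#' @param flash_amplitude peak intensity of a flash, in counts
#' @param background_level constant background, in counts
#' @param noise_sigma additive Gaussian noise sigma, in counts
#' @param frame_interval seconds per frame
#' @param flash_duration_frames frames over which a flash decays
#' @return object of class `render_params`
#' @export
render_params <- function(psf_sigma = 2, flash_amplitude = 8000,
                          background_level = 100, noise_sigma = 20,
                          frame_interval = 0.06, flash_duration_frames = 3L) {
  stopifnot(psf_sigma > 0, flash_amplitude > 0, noise_sigma >= 0,
            frame_interval > 0, flash_duration_frames >= 1)
  structure(list(psf_sigma = psf_sigma, flash_amplitude = flash_amplitude,
                 background_level = background_level,
                 noise_sigma = noise_sigma, frame_interval = frame_interval,
                 flash_duration_frames = as.integer(flash_duration_frames)),
            class = "render_params")
}

#' Render a synthetic TIRF movie from an event stream
#'
#' Each event adds a 2-D Gaussian spot at its position to the frames
#' covering its time; the amplitude decays linearly to zero over
#' `flash_duration_frames` while the spot broadens slightly, emulating a
#' fusion flash that starts as a tight circle and dissipates. Additive
#' Gaussian noise over a constant background is applied to every frame.
#'
#' @param events event data frame (needs time_s, x_px, y_px); the
#'   recording duration is taken from its `duration` attribute unless
#'   `duration` is given
#' @param geometry an `islet_geometry` (for the field size)
#' @param params a `render_params`
#' @param seed integer seed for the noise (NULL = current RNG)
#' @param duration recording length in s
#' @return numeric array (ny, nx, frames) of intensities in counts,
#'   with attribute `frame_interval`
#' @export
render_movie <- function(events, geometry, params = render_params(),
                         seed = NULL, duration = attr(events, "duration")) {
  stopifnot(inherits(params, "render_params"))
  if (is.null(duration)) duration <- max(events$time_s, 1)
  nx <- geometry$field_size[1]; ny <- geometry$field_size[2]
  if (nrow(events) > 0) {
    if (any(events$time_s < 0 | events$time_s > duration))
      stop("event times outside [0, duration]")
    if (any(events$x_px < 0 | events$x_px >= nx |
            events$y_px < 0 | events$y_px >= ny))
      stop("event positions outside the field")
  }
  n_frames <- as.integer(ceiling(duration / params$frame_interval))
  if (!is.null(seed)) set.seed(seed)
  stack <- array(0, dim = c(ny, nx, n_frames))
  for (i in seq_len(nrow(events))) {
    f0 <- floor(events$time_s[i] / params$frame_interval) + 1L
    for (k in seq_len(params$flash_duration_frames) - 1L) {
      f <- f0 + k
      if (f > n_frames) break
      amp <- params$flash_amplitude *
        (1 - k / params$flash_duration_frames)
      sig <- params$psf_sigma * (1 + 0.5 * k)
      stack[, , f] <- stack[, , f] +
        .gaussian_spot(ny, nx, events$x_px[i], events$y_px[i], amp, sig)
    }
  }
  # per-frame noise keeps peak memory at one frame, not one stack
  for (f in seq_len(n_frames)) {
    stack[, , f] <- stack[, , f] + params$background_level +
      if (params$noise_sigma > 0)
        stats::rnorm(ny * nx, 0, params$noise_sigma) else 0
  }
  attr(stack, "frame_interval") <- params$frame_interval
  stack
}

# additive Gaussian spot on an ny x nx frame, restricted to a +-4 sigma
# window; x, y are 0-based pixel-center coordinates
.gaussian_spot <- function(ny, nx, x, y, amplitude, sigma) {
  out <- matrix(0, ny, nx)
  half <- ceiling(4 * sigma)
  cx <- round(x); cy <- round(y)
  xs <- max(0, cx - half):min(nx - 1, cx + half)
  ys <- max(0, cy - half):min(ny - 1, cy + half)
  gx <- exp(-(xs - x)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y)^2 / (2 * sigma^2))
  out[ys + 1, xs + 1] <- amplitude * outer(gy, gx)
  out
}

#' Write a movie stack as a multi-page TIFF
#'
#' Intensities are scaled by 1/65535 and stored as 16-bit pages;
#' [read_movie()] undoes the scaling. Negative values are clamped to 0.
#'
#' @param stack numeric array (ny, nx, frames)
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_movie <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(f)
    pmin(pmax(stack[, , f], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF movie written by [write_movie()]
#' @param path TIFF path
#' @param frame_interval seconds per frame to attach to the stack
#' @return numeric array (ny, nx, frames) in counts
#' @export
read_movie <- function(path, frame_interval = 0.06) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                            length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]] * 65535
  attr(stack, "frame_interval") <- frame_interval
  stack
}

#' Write an event table to CSV
#' @param events event data frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#' @param path CSV path
#' @return event data frame (requires at least time_s, x_px, y_px)
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("event CSV must have columns: ", paste(need, collapse = ", "))
  df
}
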