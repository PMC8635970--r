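# Shared fixture builders. All synthetic, generated in code at test time.

# a preset stripped down for targeted checks
preset_with <- function(base = "control_high", ...) {
  p <- condition_preset(base)
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

flat_profile <- function() biphasic_profile(peak1_amp = 0, peak2_amp = 0)

# square cell ROI with corner (x0, y0) and side s
square_roi <- function(x0, y0, s, islet_id = "i1", cell_id = "c1") {
  cell_roi(islet_id, cell_id,
           rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s)))
}

# minimal single-cell geometry covering most of a field
one_cell_geometry <- function(field = c(128L, 128L), pixel_size = 0.16,
                              islet_id = "i1") {
  structure(list(islet_id = islet_id,
                 cells = list(square_roi(4, 4, field[1] - 8,
                                         islet_id = islet_id)),
                 pixel_size = pixel_size, field_size = field),
            class = "islet_geometry")
}

# hand-constructed clustered event table: two tight spatial clusters and
# two stray events in one cell
toy_clustered_events <- function() {
  ev <- data.frame(
    time_s = c(10, 12, 15, 100, 130, 150, 300, 400),
    x_px = c(10, 10.5, 11, 60, 60.4, 59.6, 30, 90),
    y_px = c(10, 10.4, 9.6, 60, 60.5, 59.5, 80, 20),
    islet_id = "i1", cell_id = "c1",
    true_source = c(rep("hotspot_c1_1", 3), rep("hotspot_c1_2", 3),
                    "scatter", "scatter"))
  attr(ev, "duration") <- 600
  attr(ev, "pixel_size") <- 0.16
  cluster_events(ev, cluster_params())
}
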