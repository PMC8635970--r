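# hotspotr

Spatiotemporal analysis of glucose-stimulated insulin secretion "hot
spots" from TIRF recordings of zinc-dye flashes.

Pancreatic β-cells report each insulin-granule fusion as a brief
fluorescence flash when imaged by TIRF microscopy with a
cell-impermeant zinc dye. `hotspotr` turns such movies — or synthetic
stand-ins with known ground truth — into quantitative answers to three
questions:

1. **Which cells secrete?** Flash detection (frame subtraction,
   grouped max projection, thresholded local-maxima search with
   non-maximum suppression), assignment of events to β-cell ROIs, and
   per-islet percentages of secreting cells.
2. **Is secretion spatially organized?** Density-based clustering
   (DBSCAN; radius 9 px = 1.44 µm, minimum 3 events) identifies hot
   spots, and a Monte-Carlo null under complete spatial randomness
   quantifies how many clusters of each size arise by chance,
   justifying the ≥ 3-event reporting rule via
   `min_reportable_cluster_size()`.
3. **Do larger hot spots secrete faster?** Within-cluster waits `w`
   pooled by cluster size `S` are modeled as

   `w ~ Exponential(α + β·S)`, with `α, β ~ HalfNormal(0.1)`,

   sampled by MCMC (4 chains), reported as 95% highest-density
   posterior intervals, and compared by WAIC against the
   size-independent null `w ~ Exponential(α)` (positive ΔWAIC favors
   size dependence). Plain exponential wait-time fits with KS goodness
   of fit cover the non-Bayesian kinetics.

The package is organized as an analysis workflow: every computation
lives in `R/` as a tested function; the numbered scripts under
`analysis/` are thin drivers that run the stages end to end and write
tables under `results/`. The methods vignette
(`vignettes/hotspot-analysis.Rmd`) documents the models, conventions,
defaults and their limits.

## Worked example

Simulate a 16-islet high-glucose control study, assign and cluster the
events, and summarize:

```r
library(hotspotr)

study <- simulate_study("control_high", n_islets = 16, n_cells = 20, seed = 1)
rois  <- unlist(lapply(study$geometries, `[[`, "cells"), recursive = FALSE)
asg   <- assign_events(study$events, rois)
ev    <- cluster_events(asg$events, cluster_params())
cells <- summarize_cells(ev, rois)
mean(summarize_islets(cells)$pct_cells_with_event)
#> [1] 44.6875
```

About 42% of cells secrete at least once — the activation percentage
the control-high preset encodes. Running the full driver chain
(`Rscript analysis/01_simulate.R` … `07_fluorescence.R`) prints, among
others:

```
control_high   41.6% cells secreting, 41.6% with a hot spot, 0.83 clusters/cell
noc_high       64.4% cells secreting, 64.4% with a hot spot, 2.02 clusters/cell
taxol_high     26.9% cells secreting, 23.8% with a hot spot, 0.44 clusters/cell
```

(microtubule depolymerization by nocodazole recruits more secreting
cells and more hot spots per cell; taxol stabilization suppresses
both), the chance-cluster null table with

```
minimum reportable cluster size at typical secretion levels: 3
```

a detection score on a rendered 2500-frame movie

```
detected 67 events: recall 0.957, precision 1.000
```

and per-condition size-rate fits such as

```
noc_high   beta 95% HDPI [0.0016, 0.0018] (strictly > 0), delta WAIC 849.6 (n = 3586 waits)
```

i.e., in the simulated data larger clusters secrete at measurably
faster rates (the realized per-size increment is smaller than the
generator's nominal β because biphasic thinning stretches waits; see
the vignette).

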