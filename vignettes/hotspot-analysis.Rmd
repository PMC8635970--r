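---
title: "Methods: detecting and modeling insulin secretion hot spots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and modeling insulin secretion hot spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pancreatic beta-cells secrete insulin in discrete exocytic events. When
islets are imaged by TIRF microscopy in the presence of a
cell-impermeant zinc dye, each granule fusion produces a brief
fluorescence flash (zinc is co-packaged with insulin), so a movie of an
islet's footprint is a spatiotemporal point process of secretion
events. Two features of that process carry the biology: *which* cells
secrete at all (population heterogeneity), and *where and when* events
recur within a cell (secretion "hot spots" and the biphasic time course
of glucose-stimulated secretion). `hotspotr` implements the complete
quantitative chain from raw movie to posterior inference, together with
a synthetic-data generator so that every stage is testable against
known ground truth.

## Movie processing and flash detection

Raw frames are pairwise subtracted in signed floating point (negative
values kept), then reduced by grouped maximum projection —
non-overlapping groups of 5 frames at 60 ms give the 300 ms resolution
at which events are analyzed; a final partial group is projected as-is.
Flashes are then detected per projected frame:

* pixels above `noise_level` (default 5000 counts) are candidates;
* greedy non-maximum suppression in descending intensity keeps
  candidates with no stronger kept candidate within `search_range`
  (default 6 px, Euclidean);
* each kept candidate is reported once with an intensity-weighted
  centroid over the $(2r+1)^2$ window (negative residuals are ignored
  in the weighting, the window is clipped at field borders);
* a candidate within `search_range` of an event reported in the
  immediately preceding projected frame is treated as residual signal
  of the same flash and suppressed — a flash is "present in one frame
  only" at 300 ms resolution.

The original analysis was semi-manual (an operator seeded the maxima
search and rescued rare donut-shaped events by hand); this
implementation is fully automated with the same threshold and radius
constants, so its accuracy is assessed against simulated ground truth
(recall and precision $\geq 0.9$ at default render settings) rather
than against manual counts. The threshold is applied to the projected
difference stack — the object that is actually analyzed — and is
exposed in `detection_config()`.

## Event assignment and hot-spot clustering

Events are assigned to hand-outline-style cell ROIs by a
point-in-polygon test with a *closed* boundary (on-edge points count as
inside); events inside no beta-cell are discarded and counted, and
events inside several overlapping ROIs go to the nearest-centroid ROI.
In pooled multi-islet tables, events are only matched against ROIs of
their own islet.

Within-cell events are clustered by density-based scanning (DBSCAN) on
the 2-D positions only — time is ignored, because hot spots are defined
as *spatial* loci of recurrent secretion over the whole recording. The
defaults are a 9 px (1.44 µm) search radius and a minimum neighborhood
of 3 events *counting the point itself*, so the minimum cluster size is
3. Two conventions deserve note:

* the radius is specified in pixels (9 px) rather than micrometres
  (1.5 µm); the two published forms disagree by 4% and the pixel form
  is used because the clustering operated in pixel units — the
  micrometre variant is available via `distance_space = "um"`;
* border points reachable from two clusters are assigned to the
  cluster of the earliest core point in event-time order, which makes
  the partition deterministic and independent of input order. An
  independent brute-force implementation (explicit neighborhood graph
  plus breadth-first components) is kept in the test suite as the
  oracle.

## Why clusters need at least three events

The reporting rule (hot spot = cluster of $\geq 3$ events) is
justified by a Monte-Carlo null: events placed uniformly at random
(complete spatial randomness) in an in-silico cell, clustered with the
same radius, with clusters of size $\geq k$ tallied per cell. For this
null `min_points` drops to 2 so that chance *pairs* are countable, and
a pairwise analytic check ($\Pr(|X_1 - X_2| \le \varepsilon) \approx
\pi\varepsilon^2 / A$ for cell area $A \gg \pi\varepsilon^2$) pins the
simulation to closed form.

In a 120 µm² cell footprint at typical secreting-cell event counts
(roughly 2–10 events), chance pairs are prevalent (about 1.6 per cell
at 10 events) while chance triples are rare (0.035 per cell at 5
events) — hence three is the smallest defensible reporting size, as
`min_reportable_cluster_size()` returns at the default tolerance of
0.05 expected chance clusters per cell. One honest caveat: this
separation holds at *typical* secretion levels, not everywhere. The
expected number of chance triples grows like
$0.29\,n^3 (\pi\varepsilon^2/A)^2$, so at the extreme top of the
observed range (40 events in a single 120 µm² footprint) chance
triples exceed one per cell for *any* cell-sized area; the acceptance
checks therefore evaluate the pairs-vs-triples separation at the
typical counts and the pair prevalence at the upper range, and the
full expected-cluster table is always reported so the reader can see
where the null stops protecting the rule. The in-silico cell geometry
is configurable (observed polygons or an area-matched disk); the null
uses uniform placement with no intensity inhomogeneity.

## Wait-time kinetics

If secretion events are independent, the waits between successive
events (per cell, per cell excluding clustered events, or within each
cluster) are exponential. Waits are computed per group on
ascending-sorted times and pooled across groups of a condition;
`fit_exponential()` returns the maximum-likelihood rate
$\hat\lambda = 1/\bar w$ with a zero location offset (a free offset is
physically meaningless for waits) and a one-sample KS test against
$\mathrm{Exp}(\hat\lambda)$ with the asymptotic p-value. Testing
against a rate estimated from the same sample makes that p-value
conservative (the Lilliefors effect); this behavior is kept
deliberately because it is how the original fits were assessed, and a
parametric-bootstrap alternative (`ks_method = "bootstrap"`) is
provided as the corrected version. With the rate supplied externally
the test is exact in calibration: the suite checks a 5% ± 2% type-I
error over 1000 replicates.

Timing structure is summarized by half-open 30 s histograms (optionally
normalized to percent of condition total) over five strata: all events,
clustered, non-clustered, and the first or last event of each cluster;
cluster lifetimes carry flags for initiation before the first-phase
boundary (default 300 s, from the 2–4 min and 9–10 min peak windows;
configurable, as is an optional stimulation-time offset — the recording
starts within about 2 min of stimulation and the default offset is 0).

## The size-dependent secretion-rate model

To ask whether larger hot spots secrete *faster*, within-cluster waits
pooled by cluster size $S$ are modeled as

$$ w \sim \mathrm{Exponential}(\alpha + \beta S), \qquad
   \alpha, \beta \sim \mathrm{HalfNormal}(0.1), $$

so the mean wait is $1/(\alpha + \beta S)$ and $\beta > 0$ means faster
secretion from larger clusters. The half-normal priors (sd 0.1) are
weakly informative and enforce a positive rate. Posteriors are sampled
with JAGS, 4 chains of 4000 post-warmup draws each (1000 warmup;
whether the published "4000 samples" included warmup is not stated, so
4000 is treated as post-warmup and both are configurable). Inference
is reported as 95% highest-density posterior intervals — the narrowest
window of $\lceil 0.95 n \rceil$ consecutive sorted draws, first window
on ties — and the model is compared against the size-independent null
($w \sim \mathrm{Exponential}(\alpha)$) by WAIC computed from pointwise
log-likelihoods with the pointwise-variance penalty (the published
variant is unstated). The difference is signed so that *positive favors
the size-dependent model*. Each condition is fit separately; there is
no hierarchical pooling. A convergence gate (split-$\hat R < 1.01$,
effective sample size $\geq 400$) is attached to every fit as a
warning — the original analysis reported no diagnostics, so this gate
is an addition, not a reproduction.

Calibration at desk scale: with waits simulated at
$\alpha = 0.05, \beta = 0.02$ over sizes 3–8 ($n = 200$), both 95%
HDPIs cover the truth in $\geq 90/100$ replicate fits; with
$\beta = 0$ the WAIC difference favors the null on average and the
$\beta$ interval abuts zero; with $n = 2000$ size-dependent waits the
$\beta$ interval is strictly positive.

## The synthetic-data generator

The generator defines the study conditions everything else is tested
under; its defaults are fixed once and are not tuning knobs.

* **Geometry.** An islet footprint is a disk tiled into simple
  polygons by a bounded Voronoi tessellation of random seeds (the disk
  radius follows from the target mean cell footprint, default 120 µm²
  of an attached beta-cell, capped to stay inside the field; pixel
  size defaults to 0.16 µm/px, i.e. 9 px = 1.44 µm). No published
  in-silico cell geometry exists, so footprints are configurable, not
  calibrated.
* **Activation.** Each cell secretes at all with probability
  `p_active` — 0.42 (control), 0.66 (nocodazole), 0.27 (taxol, similar
  to low glucose) in high glucose, the observed secreting-cell
  fractions.
* **Hot spots.** Active cells draw a hot-spot count (single-spot
  dominated in control, multi-spot under nocodazole, suppressed under
  taxol), a center uniform in the cell, and a target size from a
  decaying distribution over 3–8. Event positions are isotropic
  Gaussian around the center with $\sigma = 0.3$ µm truncated to the
  cell, chosen so that essentially all within-spot pairs fall inside
  the 1.44 µm clustering radius and simulated spots are recoverable by
  the stated parameters. Event times are cumulative exponential waits
  at rate $\alpha + \beta\,\mathrm{size}$ (defaults 0.05 and 0.02
  events/s) — size-first simulation, mirroring the per-size wait-time
  analysis rather than a self-exciting process.
* **Scatter.** Non-clustered events are a Poisson process (peak rate
  `scatter_rate`, default 0.05 events/s per cell) with uniform
  positions.
* **Biphasic timing.** Both processes are thinned by a
  baseline-plus-two-Gaussian-bumps profile with peaks at 180 s and
  570 s (the 2–4 min and 9–10 min windows); only the peak windows are
  published, so the functional form is the package's choice. Thinning
  modulates rates relative to the profile maximum, which also means
  realized within-cluster waits in full simulations are *not* cleanly
  exponential — the model-calibration studies therefore draw waits
  directly from the generative law (`simulate_size_waits()`), and the
  full pipeline is judged on counts, percentages and cluster recovery
  instead.
* **Rendering.** Movies add a 2-D Gaussian spot per event (amplitude
  8000 counts decaying linearly over 3 frames while broadening,
  emulating a flash that starts tight and dissipates) over a constant
  background (100) with Gaussian noise (sd 20) at 60 ms/frame.
  No photophysics is modeled: no bleaching, no evanescent-field depth,
  no non-beta-cells, no 3-D geometry.

What passing tests on these synthetics do *not* show: robustness to
drift, uneven illumination, photobleaching, donut-shaped flashes,
overlapping real cells, or manual-curation idiosyncrasies of real
recordings.

## Numerical choices and degenerate inputs

* Polygon operations use exact shoelace areas and a closed-boundary
  point test with a $10^{-9}$-scaled tolerance; polygon simplicity is
  enforced on ROI input and degenerate (< 3 vertex) outlines are
  rejected with the offending cell named.
* Clustering of 0 or 1 events returns all-noise; empty detection
  output is valid; an islet summary over zero secreting cells reports
  the secreting-cell percentage as missing rather than 0.
* Timing histograms use half-open bins $[lo, hi)$ throughout; an event
  at exactly 150 s falls in $[150, 180)$.
* `fit_exponential()` refuses all-zero waits (degenerate MLE); KS
  warnings from tied projected event times are suppressed by design.
* Seeds: every stochastic entry point takes an explicit seed; the
  pipeline derives per-stage seeds from one master seed; JAGS chains
  get Mersenne-Twister streams seeded as `seed * 1000 + chain`.

## Problem sizes

The shipped analysis scripts and checks run at desk scale, chosen so a
full pass stays interactive on one CPU: 16 islets x 20 cells per
condition for population summaries, 1000 replicates for the
chance-cluster null (4000 for the analytic pair check), 100 replicate
fits for HDPI coverage and 50 for null recovery at 4 chains x 1000
draws (the per-condition fits in `analysis/06_rate_model.R` use the
full 4 x 4000), and one 2000-frame 256 x 256 rendered movie with 100
flashes for detection scoring.

## Known limitations

* The flash detector has no donut/ring classifier, no drift or
  photobleach correction, and no sub-pixel PSF fitting; it reproduces
  the original constants, not the operator.
* The chance null assumes spatial uniformity within the cell; real
  secretion is already non-uniform, so the null is conservative about
  calling hot spots at the cell scale but says nothing about sub-cell
  intensity gradients.
* The exponential wait-time model ignores the non-stationarity induced
  by biphasic stimulation; fits pooled over a whole recording mix the
  two phases.
* WAIC comparisons between barely-identified models (few waits, few
  distinct sizes) are noisy; the convergence gate flags, but cannot
  rescue, such fits.
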