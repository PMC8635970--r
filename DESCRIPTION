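Package: hotspotr
Title: Spatiotemporal Analysis of Insulin Secretion Hot Spots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Detection and spatiotemporal analysis of glucose-stimulated
    insulin secretion events recorded by TIRF imaging of zinc-dye flashes.
    Provides a synthetic-data generator for in-silico islets and rendered
    movie stacks, automated flash detection (frame subtraction, grouped
    maximum projection, thresholded local-maxima search), assignment of
    events to beta-cell ROIs, density-based clustering of events into
    secretion hot spots, Monte-Carlo null models for chance clustering
    under complete spatial randomness, exponential wait-time kinetics with
    Kolmogorov-Smirnov goodness of fit, biphasic timing histograms, and a
    Bayesian generalized linear model relating within-cluster secretion
    rate to cluster size (half-normal priors, highest-density posterior
    intervals, WAIC model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
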