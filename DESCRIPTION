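Package: phylosprint
Title: Phylogenetic Comparative Analysis of Sprint Speed, Leg Spination
    and Web Use in Spiders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline from raw tracking coordinates and leg
    measurements to phylogenetic comparative conclusions. Extracts sprint
    speed from frame-by-frame trajectories (spline smoothing with an N/2+1
    knot rule), computes a front-leg spination index, fits two-state Markov
    models of web evolution (equal rates, all rates different, and a
    Dollo-constrained model forbidding web regain), samples stochastic
    character maps and counts losses and gains, fits Brownian motion,
    Ornstein-Uhlenbeck, early-burst and Pagel's lambda models to continuous
    traits with AICc model selection, runs phylogenetic linear regressions
    with lambda or OU residual structure, and estimates group mean-difference
    effect sizes with bootstrap confidence intervals. A synthetic-data module
    generates trees, trait data and trajectories with known ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
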