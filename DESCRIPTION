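Package: sleeptopo
Title: Sleep EEG Power Topography and Cluster-Corrected Group Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-density sleep EEG power topography:
    conditioning of multichannel recordings (single-pole high-pass, zero-phase
    Kaiser FIR band-pass, amplitude-based artifact masking, spherical-spline
    channel interpolation, average reference), extraction of stage-labelled
    6-second analysis epochs from a 30-second hypnogram, Welch power spectra
    with band and 1-Hz-bin topographic maps (absolute and z-scored), sleep
    cycle segmentation, nonparametric cluster-based permutation tests on the
    electrode adjacency graph (and their 1-D analogue over frequency bins),
    mixed between-within ANOVA with Huynh-Feldt correction, and Spearman or
    partial Spearman clinical correlations. A seeded synthetic-cohort
    generator reproduces the statistical structure the analysis assumes
    (1/f background, stage-gated oscillations, localized group effects,
    homeostatic cycle decline, covariate coupling) so the whole pipeline is
    testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
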