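Package: foldq
Title: Folding-Pathway Kinetics from Coarse Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of coarse protein folding trajectories through the
    fraction of native contacts (Q) between secondary-structure elements.
    Detects per-element-pair folding transitions from smoothed derivatives of
    Q time series, clusters transition times by Gaussian kernel density
    estimation to call two-state versus multistate kinetics, and evaluates the
    calls against formal kinetics labels, folding rate constants and
    hydrogen-deuterium exchange intermediate annotations. Includes a synthetic
    trajectory generator with programmable phase schedules so that every stage
    of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
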