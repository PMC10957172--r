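Package: vtamemcode
Title: Trajectory-Specific Coding Analysis for Midbrain Single-Unit
    Recordings in a T-Maze Memory Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing extracellular single-unit recordings from
    optogenetically tagged ventral tegmental area (VTA) dopamine and GABA
    neurons while mice run a figure-eight T-maze memory task.  The package
    linearizes trial trajectories into position bins, estimates
    occupancy-normalized firing-rate maps, identifies trajectory-specific
    (left versus right) firing with a label-permutation test, fits a
    Gaussian generalized linear model of firing rate on trajectory-position
    and speed polynomials with shuffle-calibrated predictor significance,
    classifies reward-epoch responses in the time domain, and detects
    light-responsive (ChR2-tagged) units from pulse-aligned histograms
    against a resampled baseline confidence band.  A synthetic-session
    generator with planted ground truth makes every stage testable without
    in-vivo recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
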