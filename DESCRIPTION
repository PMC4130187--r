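Package: immunecouple
Title: Coupled Tissue / Lymph-Node Simulation of the Immune Response to a
    Bacterial Antigen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the innate and adaptive immune response to a
    replicating bacterial antigen by coupling a three-dimensional
    reaction-diffusion model of the tissue (antigen, resting and activated
    macrophages, antibodies) to a well-mixed ordinary-differential-equation
    model of the nearest lymph node (antigen-presenting macrophages, T and B
    lymphocytes, plasma cells, antibodies).  The two compartments exchange
    cells and antibodies through explicit blood- and lymph-vessel indicator
    fields.  Includes an explicit-Euler co-simulation engine, scenario
    presets (antigen only, innate only, fully coupled), a
    one-factor-at-a-time sensitivity analysis, and writers for time-series
    CSV and legacy-VTK field snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
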