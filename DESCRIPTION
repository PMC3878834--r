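Package: colonycal
Title: Calibrating Lattice Models of Cell Colony Expansion from Barrier
    Assay Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and calibrating a lattice exclusion-process
    model of cell colony expansion in circular barrier assays. Agents move
    with an adhesion-modulated motility probability and proliferate under
    crowding, and colonies are summarised by four assay statistics: the
    equivalent radius of the detected leading edge, transect cell density
    profiles, the percentage of isolated cells (a clustering measure), and
    subregion cell density counts. Normalised least-squares error surfaces
    over cell diffusivity and adhesion strength support grid-sweep
    calibration and expose which data types identify which parameters;
    logistic growth fits estimate the proliferation rate. A synthetic-data
    generator reproduces the replicate structure of the assay so the whole
    pipeline can be exercised without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
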