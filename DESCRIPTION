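Package: episcope
Title: Docking-Guided Design of Antigen Variant Panels for Antibody
    Epitope Localization
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes antibody epitopes by treating an ensemble of
    antibody-antigen docking poses as competing binding hypotheses and
    designing a minimal panel of multi-mutation antigen variants such that
    every pose is predicted to be disrupted by at least one variant.
    Provides structure input and solvent-accessibility computation,
    docking-footprint and interface (f_nat) metrics, homolog-restricted
    disruptive mutation design under stability and geometric-spread
    filters with Pareto selection, Hausdorff-distance K-medoids clustering
    and minimal covering-panel selection, multi-antibody pooling and
    in-silico epitope binning matrices, a random-design baseline, and a
    synthetic scenario generator for end-to-end testing without external
    structure downloads.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
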