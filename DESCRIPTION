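Package: sptkit
Title: Single-Particle Tomography Toolkit for Chaperonin Subtomogram Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Missing-wedge-aware single particle tomography (SPT) in R:
    simulation of subtomogram cohorts of a barrel-shaped double-ring
    chaperonin with a single-axis missing wedge, constrained cross-correlation
    alignment, hierarchical ascendant classification and wedge-compensated
    averaging, reference-ranked quintile classification of cavity-empty
    versus cavity-occupied particles with mask-based t-test validation,
    rotational point-group symmetry and Fourier shell correlation analysis,
    D8-restricted localization of intra-cavity density, and three estimators
    of encapsulated mass scaled by the complex's reference mass.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
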