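Package: dasyrf
Title: Random-Forest Dasymetric Population Mapping and Covariate-Class
    Importance Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits random-forest dasymetric population models on zonal
    summaries of gridded geospatial covariates and census counts, computes
    out-of-bag permutation importance (per-cent increase in mean squared
    error) with iterative elimination of negative-importance covariates,
    predicts a pixel-level density weighting layer and redistributes
    census counts mass-preservingly onto the grid. Standardizes
    heterogeneous covariate names into variable classes, computes the
    weighted importance rank (WIR) per country, and compares WIR across
    covariate classes, regions and countries with tie-corrected
    Kruskal-Wallis tests and post hoc Dunn tests under Holm's correction.
    Includes a synthetic-country generator (covariate grids, admin zones,
    census tables with a known density-generating model) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
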