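Package: metabmarker
Title: Primary and Secondary Metabolomic Marker Discovery for Two-Group Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers two complementary kinds of metabolomic markers that
    separate a case group from a control group in a samples-by-metabolites
    abundance matrix (e.g. targeted LC-MS/MS peak areas). Primary markers are
    small metabolite combinations whose concentrations jointly discriminate the
    groups; they are found by a genetic algorithm whose fitness is the minimum
    cross-validation-fold accuracy of a gradient-boosted tree classifier.
    Secondary markers are metabolites whose correlation structure, learned from
    controls by an ensemble of denoising autoencoders, is disrupted in cases;
    they are flagged by rank tests on reconstruction errors with false
    discovery rate control and a consensus count over the ensemble. Also
    provides median imputation and log preprocessing, nonparametric screening
    with Benjamini-Hochberg or Benjamini-Yekutieli correction, local
    hypergeometric pathway over-representation analysis, and a synthetic-data
    generator with planted mean-shift and correlation-break markers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
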