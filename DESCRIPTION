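Package: agrostack
Title: Meta-Analysis of Stacked Sustainable Agricultural Practices and
    Agroecosystem Services
Version: 0.1.0
Authors@R:
    person("Agrostack", "Developers", email = "dev@agrostack.invalid",
           role = c("aut", "cre"))
Description: Tools to quantify how the number of simultaneously applied
    sustainable agricultural practices affects agroecosystem services in
    paired sustainable-versus-intensive field comparisons.  Implements
    binary practice coding and counting, log response ratio (LnRR) effect
    sizes with bootstrap confidence intervals, aridity stratification,
    variance partitioning of service responses over four environmental
    predictor blocks (spatial, climate, soil, vegetation) on adjusted
    R-squared, variance inflation factor screening, Spearman association
    screens, and random-forest spatial prediction with permutation
    importance and a Mahalanobis applicability mask.  Ships a synthetic
    database generator with known ground truth so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
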