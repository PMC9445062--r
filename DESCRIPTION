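Package: metabcc
Title: Case-Cohort Metabolomic Association Scans and Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prospective case-cohort analyses of high-dimensional
    metabolic biomarker panels. Implements Cox proportional-hazards
    estimation under the Prentice pseudo-partial likelihood with robust
    (sandwich) variance, per-biomarker association scans with
    Benjamini-Hochberg false discovery rate control across nested
    covariate-adjustment tiers, subgroup analyses with Cochran Q
    heterogeneity, reverse-causality sensitivity analyses, cuboid-traversal
    biomarker selection for building enhanced risk-prediction models, and
    comparison of model discrimination via an inverse-probability-weighted
    concordance index. A synthetic cohort generator with block-correlated
    biomarkers, adiposity-dependent biomarker levels and Weibull
    proportional-hazards event times supports method validation when the
    motivating cohort data are access-controlled.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, tools, yaml, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), survival, optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
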