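Package: protclock
Title: Proteomic Age Clocks with Shadow-Feature Selection and Outcome Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds protein-based chronological age predictors from NPX-scale
    proteomic matrices using gradient-boosted trees, selects age-informative
    proteins by Boruta shadow-feature testing and SHAP-guided recursive
    elimination, computes out-of-fold proteomic age gaps, and runs the
    downstream epidemiology: covariate-adjusted association scans with
    Benjamini-Hochberg correction, tiered Cox proportional-hazards models with
    prevalent-case exclusion, Kaplan-Meier cumulative incidence by gap decile,
    and SHAP-interaction protein networks. Ships a synthetic multi-cohort
    generator with known ground truth so the whole pipeline is testable
    without access-controlled biobank data, plus an exact double-precision
    TreeSHAP engine for attribution and interaction values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xgboost,
    data.table,
    survival,
    glmnet,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
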