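Package: gutmaturity
Title: Microbiota Maturity and Dysbiosis Analysis for Pediatric IBD Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse gut microbiome maturation in longitudinal
    pediatric cohorts with inflammatory bowel disease (IBD), including very
    early onset IBD. Provides a synthetic cohort generator with known ground
    truth, taxa-table input and filtering, alpha and Bray-Curtis beta
    diversity with a healthy-reference dysbiosis score, zero-inflated beta
    regression with subject random effects for longitudinal per-taxon
    testing, a Random-Forest microbiota maturity index (MMI) with nested
    cross-validation panel selection and spline-normalised Relative MMI, a
    healthy-constrained two-component mixture model fitted by
    expectation-maximisation, and ROC/rank-based evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    glmmTMB,
    lme4,
    pROC,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
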