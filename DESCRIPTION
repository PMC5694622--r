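Package: trivus
Title: Verification-Bias-Corrected ROC Surface and VUS Analysis for
    Three-Class Diagnostic Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the three-class receiver operating characteristic
    (ROC) surface and the volume under it (VUS) for a continuous diagnostic
    test when the gold-standard disease status is missing at random because
    only a subset of subjects undergoes disease verification.  Implements
    five bias-corrected estimators (full imputation, mean score imputation,
    inverse probability weighting, semiparametric efficient, and K
    nearest-neighbor), jackknife and bootstrap variance estimation,
    confidence intervals on the natural and logit scales, the one-sided test
    of the useless-test null VUS = 1/6, bias-corrected true class fractions
    with ellipsoidal confidence regions, and a synthetic-data generator with
    exact and Monte-Carlo truth oracles for simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    nnet,
    MASS,
    parallel,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
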