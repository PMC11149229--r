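Package: raremix
Title: Bayesian Recalibration and Mixture Models for Rare-Disease Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for developing and recalibrating clinical prediction
    models for rare diseases by pooling an enriched case-control training
    dataset with a population-representative calibration dataset. Implements
    conversion-table (sensitivity/specificity) prevalence adjustment,
    likelihood-ratio offset updating, Bayesian re-estimation, joint
    hierarchical shrinkage recalibration with full uncertainty propagation,
    and a hierarchical mixture model that constrains predictions for
    biomarker-inconsistent subjects through an informative Beta prior and
    marginalises over missing biomarker status at prediction time. Includes
    a synthetic cohort generator emulating a case-control study and a
    biomarker-screened population cohort, plus discrimination, calibration
    and bootstrap-stability assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    coda,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
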