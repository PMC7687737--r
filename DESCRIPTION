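Package: readmitclust
Title: Sampling Strategies and Cluster-Aware Estimation for Hospital
    Readmission Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how discharge sampling strategy (first
    discharge per patient versus all discharges) and clustering-aware
    estimation (ordinary logistic regression, generalized estimating
    equations with an exchangeable working correlation, and
    cluster-weighted GEE) affect observed 30-day readmission rates and
    the internally validated performance of readmission risk models.
    Includes a synthetic clustered-cohort generator with informative
    cluster size (a shared patient-level frailty drives both the number
    of discharges and the readmission risk), cohort-construction rules
    (merging of near-immediate readmissions, 30-day outcome labeling),
    two-stage variable selection, five performance measures (C statistic,
    outcome correlation, coefficient of discrimination, Brier score and
    scaled Brier score), and a resampling experiment over cohort sizes
    with slope analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
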