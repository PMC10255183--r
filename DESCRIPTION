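Package: LipoProfile
Title: Stability-Selected Lipoprotein Particle Profiles for Telomere-Related Outcomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives sparse lipoprotein particle profiles associated with leukocyte
    telomere length and telomerase-complex gene expression (TERT, WRAP53) in small
    cohorts. Implements the full analysis chain: iterative random-forest imputation of
    NMR lipoprotein panels, rank-based inverse normal transformation, robust outlier
    exclusion at the 99th percentile, chained-equation imputation of outcomes,
    leave-one-out cross-validated Lasso regression with bootstrap-aggregated penalty
    tuning, stability selection of consistently retained predictors, weighted profile
    scores, and Fisher-z correlation inference. Ships a synthetic cohort generator
    emulating a prediabetic study population so every stage is testable without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Regression, Metabolomics, Lipidomics, StatisticalMethod
RoxygenNote: 7.3.3
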