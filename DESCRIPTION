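Package: hdspeech
Title: Speech-Based Prediction of Clinical Severity in Huntington's Disease
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying motor-speech and cognitive-sequencing
    deficits from brief forward/backward number-counting recordings in
    carriers of the mutant huntingtin gene. Reads time-aligned Praat
    TextGrid annotations, computes 60 articulatory, phonatory, rhythm,
    sequence-error and collateral-track features (30 per task), derives
    UHDRS composites (cUHDRS, disease burden score), predicts clinical
    scores with a bounded portfolio model search and greedy ensembling,
    validates predictions with grouped repeated splits scored by MAE and
    ICC(2,1), and screens feature-striatal-volume associations with
    MICe/TICe information coefficients under maximum-statistic permutation
    correction. A calibrated synthetic-cohort generator exercises the whole
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    glmnet,
    e1071,
    ranger,
    rpart,
    signal,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, MachineLearning, Regression
RoxygenNote: 7.3.3
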