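Package: fittriage
Title: Risk Stratification and Triage of FIT-Positive Colorectal Cancer Screening Participants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying participants of a fecal immunochemical test
    (FIT) based colorectal-cancer screening programme after a positive test.
    Provides a synthetic cohort generator reproducing a published five-cluster
    population structure, preprocessing (label encoding, z-scoring, chained
    multiple imputation with Rubin pooling, bowel-preparation adequacy),
    autoencoder plus k-means patient clustering with silhouette model
    selection and feed-forward network validation, composite and simplified
    point-based malignancy risk scores with a three-tier triage grid,
    threshold-sweep diagnostic-yield and cost-per-cancer economics tables, and
    evaluation utilities (ROC/AUC with bootstrap intervals, DeLong paired
    tests, precision-recall, group-fairness metrics, completer sensitivity
    analysis and inverse-probability-of-completion weighting).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
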