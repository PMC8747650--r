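Package: rooibosclass
Title: Statistical and Machine Learning Classification of Rooibos Assay Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking machine-learning classifiers against a
    Gaussian minimum-Mahalanobis-distance baseline on small tabular
    phytochemical assay data, built around fermented (FR) versus unfermented
    (UFR) rooibos samples characterised by total phenolic content (TPC) and
    antioxidant capacity (TEAC, FRAP) in water and methanol extracts.
    Includes a multivariate Gaussian synthetic-data generator parameterised
    from published summary statistics, descriptive statistics with 95%
    confidence ellipses, per-assay ROC/AUC analysis, stratified train/test
    evaluation, and leave-one-out jackknife error bars on ML-minus-baseline
    accuracy differences.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    class,
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
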