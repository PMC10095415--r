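Package: strokeage
Title: Data-Driven Estimation of the Young Ischemic Stroke Age Cut-Point
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the age cut-point separating "young" from older ischemic
    stroke by two parallel data-driven procedures. The first maps pre-index
    ICD-9-CM/ICD-10-CM diagnosis codes to Phecodes, computes each stroke
    patient's median cosine similarity to all other same-sex patients, and
    locates the age that best separates the similarity trend by a maximally
    selected standardized Wilcoxon statistic. The second trains case/control
    classifiers (regularized logistic regression, random forest, gradient
    boosting) over nested age brackets, compares each bracket's normalized
    feature-importance vector to the all-ages reference by cosine similarity,
    and applies the same cut-point estimator to the resulting trend. A seeded
    synthetic electronic-health-record cohort generator with a planted
    change-point age makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    ranger,
    xgboost,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
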