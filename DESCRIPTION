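Package: radlabel
Title: Attention-Based Labelling and Evaluation of Neuroradiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives normal/abnormal and seven specialised abnormality labels
    (acute stroke, mass, atrophy, vascular, small vessel disease, white matter
    inflammation, encephalomalacia) from free-text neuroradiology reports with a
    contextual transformer encoder, learned attention pooling and a
    single-hidden-layer classification head, trained end-to-end with binary
    cross-entropy and Adam. Ships a seedable synthetic report-corpus generator
    with distant-negation structure, a mean-static-embedding plus N-gram
    logistic-regression comparator, patient-level repeated-split evaluation with
    DeLong tests for correlated ROC curves, Fleiss' kappa inter-rater agreement,
    corpus lexical statistics (type-token ratio, Yule's I), attention-weight
    interpretability and batch label assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
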