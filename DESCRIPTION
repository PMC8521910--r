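Package: cogtype
Title: Digital Biomarkers for Cognitive Screening from Touchscreen Typing and Written Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts keystroke-dynamics series (hold and flight times) from
    touchscreen typing sessions, estimates fine-motor-impairment severity
    indices (rigidity, bradykinesia, alternate finger tapping) with a
    one-dimensional convolutional autoencoder and fine-tuned regression
    heads, computes nine linguistic biomarkers (lexical richness, word-class
    ratios, mean dependency distance) from dependency-parsed CoNLL-U texts,
    and evaluates cascaded leave-one-subject-out classifiers of mild
    cognitive impairment with bootstrap ROC analysis and Youden-optimal
    operating points. Ships a synthetic cohort generator so the whole
    pipeline is runnable without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    class,
    randomForest,
    pROC,
    glmnet,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
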