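Package: ptcnet
Title: Paired Trial Classification for Epoched EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes stimulus categories from epoched EEG by classifying
    pairs of trials as drawn from the same or different classes, then mapping
    the pairwise decisions back to multiclass predictions with a dictionary
    of known-class exemplars. Implements the densely skip-connected
    convolutional pair comparator, three averaging variations
    (single-to-single, single-to-average, average-to-average),
    leave-one-subject-out cross-validation with dynamic balanced pair
    sampling and early stopping, linear SVM and sparse multinomial logistic
    regression baselines, and a synthetic multi-subject ERP generator so the
    full pipeline is testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    arrow,
    readr,
    withr,
    e1071,
    glmnet,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
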