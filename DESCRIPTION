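Package: stigmatext
Title: Detecting Stigmatizing and Positive Language in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating classifiers of stigmatizing
    and positive/preferred language in obstetric clinical notes. Provides
    gold-standard exemplar management with JSONL and BRAT standoff I/O,
    rule-based text normalisation and sentence windowing, a deterministic
    hashed character n-gram embedding with exact top-k cosine retrieval for
    semantic-similarity training-set expansion under human verification,
    matched negative sampling and stratified dataset splits, TF-IDF features
    with chi-squared selection feeding support vector machine, decision tree
    and random forest classifiers with stratified cross-validation and
    model-based hyperparameter search, and an evaluation harness with
    bootstrap resampling, bias-corrected accelerated (BCa) confidence
    intervals and Wilcoxon signed-rank model comparison. A synthetic
    obstetric-note corpus generator makes every stage runnable end to end
    without access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    e1071,
    rpart,
    ranger,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
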