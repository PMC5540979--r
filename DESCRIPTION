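Package: eegboost
Title: Entropy Features and AdaBoost for EEG Driver-Fatigue Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects driver fatigue from EEG recordings by extracting four
    entropy features (fuzzy, sample, approximate and spectral entropy) from
    non-overlapping 1-second windows and classifying normal versus fatigue
    epochs with a from-scratch AdaBoost ensemble over depth-limited decision
    trees. Includes zero-phase band-pass filtering and epoch windowing,
    per-subject/per-channel feature scaling, a full evaluation battery
    (error rate, precision, recall, F1, Matthews correlation, ROC/AUC,
    stratified k-fold cross-validation, paired t-tests) with parameter and
    robustness sweeps, and a synthetic two-state EEG generator plus the
    MIX(p) sine-noise benchmark process for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
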