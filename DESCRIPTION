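Package: aeegrf
Title: Classification of Amplitude-Integrated EEG Background Patterns with a
    Class-Weighted Random Forest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a 119-dimensional combined feature set (basic,
    amplitude-histogram, and approximate-entropy-selected segment features)
    from 3-hour amplitude-integrated EEG (aEEG) amplitude traces and
    classifies recordings as normal or abnormal background with a
    class-weighted random forest built from scratch: bagging, per-node random
    variable selection, weighted Gini splitting, weighted voting, out-of-bag
    (OOB) error estimation, and permutation-based feature significance.
    Includes a deterministic synthesizer of normal (continuous background)
    and abnormal (burst-suppression, low-voltage, flat) aEEG traces, tuning
    sweeps for forest size, variables-per-split and class weights, stratified
    cross-validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
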