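Package: srnaens
Title: Ensemble Learning for Bacterial Small RNA Prediction from Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts bacterial small non-coding RNAs (sRNAs) from primary
    sequence using seventeen sequence-derived feature encoders (k-mer spectrum
    profiles, mismatch profiles, reverse-complement k-mer profiles and pseudo
    di-/tri-nucleotide composition with physicochemical correlation factors),
    per-feature base classifiers (random forest, RBF support vector machine or
    a single-hidden-layer neural network), and two ensemble strategies: a
    weighted-average ensemble whose convex weights are optimized by an adaptive
    genetic algorithm maximizing AUC, and a two-stage neural ensemble that
    stacks four feature-group networks under a small meta-network. Includes
    benchmark-dataset construction from a genome plus coordinate table with
    shuffle-derived negatives, a synthetic data generator with planted k-mer
    and correlation-lag signal, stratified repeated cross-validation, and
    ROC/AUC, sensitivity, specificity and accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
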