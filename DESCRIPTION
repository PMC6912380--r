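Package: stack4mc
Title: Stacked-Ensemble Prediction of DNA N4-Methylcytosine Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-layer stacked-ensemble classifier for DNA N4-methylcytosine
    (4mC) sites in 41-bp centered-cytosine windows. Maps each window to seven
    fixed-dimension sequence encodings (k-mer composition, binary profile,
    EIIP-weighted trinucleotide frequencies, dinucleotide binary encoding with
    local position-specific dinucleotide frequencies, ring-function/hydrogen/
    chemical-property codes, and di-/tri-nucleotide physicochemical property
    products), trains four classifier families (random forest, extremely
    randomised trees, gradient boosting, RBF support vector machine) per
    encoding, and feeds the resulting 28 out-of-fold class probabilities to
    four meta-learners whose averaged vote yields the final call. Includes
    benchmark-construction utilities (greedy identity filtering, stratified
    repeated splits), a seeded synthetic-data generator with position-specific
    composition biases, and the full evaluation protocol (sensitivity,
    specificity, accuracy, Matthews correlation, AUC, repeated-split
    summaries, AUC t-tests, position-wise enrichment, probabilistic-feature
    correlation structure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    randomForest,
    ranger,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
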