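Package: fuzzybench
Title: Fuzzy Multicriteria Benchmarking of Hybrid Diagnosis Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-phase evaluation framework for clinical diagnosis
    classifiers on tabular patient data. Phase 1 preprocesses a mixed
    categorical/numeric patient table (sentinel cleaning, integer encoding,
    mean imputation, min-max normalization, SMOTE class balancing). Phase 2
    scores features against the class with three filter methods (chi-square,
    information gain, ReliefF), converts a panel of expert Likert importance
    ratings into per-feature weights with the fuzzy-weighted
    zero-inconsistency (FWZIC) method built on triangular fuzzy number
    arithmetic, and trains fifteen feature-selection-by-classifier hybrid
    models whose performance metrics form a multicriteria decision matrix.
    Phase 3 ranks the hybrids with the fuzzy decision by opinion score
    method (FDOSM): ideal-solution extraction, linguistic opinion matrices,
    triangular-fuzzy-number aggregation, and centroid defuzzification.
    A synthetic-data generator emulating an autism-spectrum-disorder
    severity study makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    e1071,
    caret,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
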