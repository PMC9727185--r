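Package: snareid
Title: SNARE Protein Identification with Physicochemical Features and
    Graph-Regularized Local-Hyperplane Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for binary classification of protein sequences, built
    around the SNARE vs. non-SNARE (vesicular transport) identification task.
    Extracts the 188-dimensional physicochemical descriptor (20 amino-acid
    composition features plus composition/transition/distribution features
    over eight residue property groupings), balances imbalanced datasets by
    SMOTE oversampling, and classifies with a graph-regularized kernel
    k-local hyperplane distance nearest-neighbor model (GHKNN), with an
    input-space HKNN baseline. Includes sensitivity/specificity/accuracy/MCC
    evaluation, stratified cross-validation, one-parameter-at-a-time sweeps,
    seeded synthetic sequence and feature-cluster generators, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
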