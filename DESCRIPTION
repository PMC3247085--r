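Package: ppispotter
Title: Active and Semi-Supervised SVM Classification of Protein
    Interaction Sentences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects sentences that assert a protein-protein interaction
    by combining pool-based active learning (breaking-ties query
    selection) with a deterministic-annealing semi-supervised support
    vector machine. Provides a nine-feature lexico-syntactic sentence
    representation (negation status via a NegEx-style detector, protein
    mention counts from gazetteer matching, interactor term and
    part-of-speech, positional features and a link-path heuristic), a
    weighted linear soft-margin SVM with sigmoid probability
    calibration, comparison baselines (supervised, random-sampling,
    cluster-then-label, break-tie active learning), synthetic corpus and
    cluster-data generators, and an evaluation harness with stratified
    cross-validation and learning curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
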