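Package: rsselect
Title: Sequence Determinants of V(D)J Recombination Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the DNA sequence specificity of V(D)J recombination from
    SARP-seq read-count libraries of 12-RSS variants randomized across the
    3' heptamer and adjoining spacer (the H4-S2 window). Provides the full
    analysis pipeline: library enumeration and one-hot encoding of
    nucleotide:position features, read-count completion and min-max
    normalization, stratified k-fold rotation cross-validation, a dense
    neural-network regressor of recombination efficiency, permutation
    Shapley attribution of the trained model, pairwise
    cooperative-relationship-vector (CRV) analysis of second-order feature
    interactions, nearest-neighbor melting-temperature regressions,
    point-mutation effect maps, external score comparison, nonamer-informed
    modeling with per-nonamer attribution rescaling, and a synthetic
    SARP-seq data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
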