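Package: prdis
Title: Specific Pathogenicity Predictors for Variants with Discordant In
    Silico Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds pathogenicity predictors specific to protein sequence
    variants on which reference in-silico tools (SIFT, PolyPhen-2, PON-P2,
    CADD, MutationTaster2) disagree.  Implements the coincidence-rule
    tri-partition of a variant set (agreement / disagreement / no-output)
    over any predictor combination, multiple-sequence-alignment derived
    biological features (BLOSUM62 element, Shannon entropy, native-residue
    PSSM log-ratio), SMOTE class rebalancing, small feed-forward neural
    network classifiers trained by stochastic gradient descent with
    momentum, replicated stratified cross-validation with six standard
    performance measures, a hybrid rule-plus-model predictor, and a
    synthetic variant-panel generator with closed-form partition
    expectations for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
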