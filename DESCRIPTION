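Package: promkin
Title: Bayesian Kinetic Classification of Promoter Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies replicated promoter-level (CAGE TSS) expression time
    courses to one of four kinetic signatures (linear, decay, dip, delayed
    peak) by nested-sampling marginal likelihoods with a synthetic-data
    complexity offset, aggregates peak calls across datasets into shared
    gene sets with known-IEG Fisher enrichment statistics, and builds a
    conserved temporal-ordering network assessed against a within-dataset
    permutation null. Includes a ground-truth-labelled synthetic cohort
    generator for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
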