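Package: idbos
Title: Confidence Scoring of Aggregated Protein-Protein Interactions by
    Occurrence-Preserving Shuffling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores literature-aggregated protein-protein interaction (PPI)
    records by comparing each pair's observed report count against an
    ensemble of randomized interaction lists that preserve every protein's
    total report count and forbid self-interactions (the IDBOS scheme:
    permutation Z-scores, empirical p-values, and average fractional ranks).
    Includes comparator rankings (hypergeometric test, raw occurrence,
    random-rank and degree-preserving rewired controls), a benchmarking
    harness (accuracy-coverage curves, average accuracy, gain over random
    ranking, top-rank overlap, domain-domain interaction enrichment),
    reference-set construction statistics (ontology ancestor closure,
    co-annotation significance, tissue-specificity Z-scores, co-expression
    scores, top-percent selection), and a synthetic generator of
    popularity-biased record streams over a planted interactome so the whole
    pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
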