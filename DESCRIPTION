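Package: funclevels
Title: Three-Level Protein Function Prediction with Domain Co-Occurrence
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) functions of proteins by combining
    three levels of evidence: profile-sequence homology search hits
    (PSI-BLAST style), profile-profile domain detection (HHSearch style),
    and aggregated neighbor-counting over per-species domain co-occurrence
    networks. Implements the confidence-scoring formulas for each level,
    three predictor strategies that combine them, CAFA-style output, and an
    evaluation framework with tie-ranked top-n and sliding-threshold
    precision/recall curves, break-even points, path-based semantic
    similarity of GO terms, and term-depth diagnostics. Ships a synthetic
    world generator (toy ontologies, multi-species proteomes, mock search
    hits with planted truth) so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
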