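Package: gwgenKit
Title: Genetic and Epigenetic Network Identification, Core Extraction and
    Drug-Target Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies condition-specific genome-wide genetic and epigenetic
    networks (GWGENs) from expression data by constrained least-squares system
    identification with AIC-based system-order detection, extracts core
    networks by principal network projection (SVD energy truncation and node
    projection scoring), performs gene-set over-representation analysis on the
    core, trains a feed-forward neural-network drug-target interaction
    classifier on labelled feature vectors, and screens candidate drugs into a
    multi-molecule combination using regulation-direction, sensitivity and
    toxicity design specifications. Ships seeded synthetic-data generators so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
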