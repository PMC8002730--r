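Package: GWGENet
Title: Genome-Wide Genetic and Epigenetic Network Identification and
    Core-Network Drug Target Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies condition-specific genome-wide genetic and
    epigenetic networks (GWGENs) from expression samples by constrained
    least squares with AIC model-order pruning of a candidate
    protein-protein interaction and gene-regulatory hypothesis network,
    extracts core networks by principal network projection (SVD energy
    ranking), compares two conditions into common and distinctive core
    sub-networks, and filters candidate drugs that reverse a biomarker
    expression signature by connectivity score and predicted LD50
    toxicity.  Ships a synthetic-data module that plants ground-truth
    networks and model-consistent expression samples so every stage can
    be validated by recovery of planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: NetworkInference, GeneRegulation, SystemsBiology, Software
RoxygenNote: 7.3.3
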