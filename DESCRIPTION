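Package: netfuse
Title: Heterogeneous Gene-Network Fusion by Inverse Mutual Rank
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates weighted gene association networks that use
    incompatible scoring systems (Pearson correlation, highest reciprocal
    rank, log-likelihood scores) onto a common inverse mutual-rank scale,
    calibrates auxiliary networks against a reference network with a
    no-intercept Gaussian GLM fitted on shared edges, and fuses them into a
    combined network scored by the summed inverse rank (SIR).  Includes
    Gene Ontology based quality evaluation (ROC/AUC, precision-recall,
    random-network control), scale-free topology assessment, seed-based
    subnetwork extraction with candidate-regulator selection, cross-species
    connectivity comparison via Fisher's exact test, a deterministic
    synthetic-network generator for benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
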