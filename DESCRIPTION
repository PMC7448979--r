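Package: sipa
Title: Simultaneous Prediction of Compound-Target-Disease Interactions in
    Pharmacology Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Large-scale inference of compound-target, compound-disease and
    disease-target interactions for multi-component (traditional-medicine)
    pharmacology networks. Combines a rule-based simple inference model (SIM)
    over a tripartite known-interaction network with a compound-target
    correlation-space predictor (CTCS-IPM) built on canonical correlation
    analysis of molecular descriptor blocks, per-anchor Euclidean-distance
    thresholds, stratified cross-validated recall evaluation, network
    expansion, and Cytoscape-convention topology statistics. Includes a
    seeded synthetic-data generator emulating correlated descriptor blocks
    and latent-proximity-driven interactions, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
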