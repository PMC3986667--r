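Package: pinweave
Title: Homology-Based Construction and Integration of Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds protein-protein interaction networks for organisms that
    lack curated interactome data by transferring interactions from model
    organisms (interolog mapping). Provides best-hit homology selection from
    BLAST tabular output, construction of per-model-organism sub-networks,
    iterative integration of sub-networks in genetic-relationship order with
    a per-turn confidence score for every node and edge, network topology
    summaries, extraction of GO-defined sub-networks such as the signaling
    sub-network, evolutionary-origin classification of proteins and
    interactions, neighbor-majority assignment of GO terms to unclassified
    proteins, and a seeded synthetic multi-organism universe generator used
    to validate every stage against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
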