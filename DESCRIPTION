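Package: cpigcn
Title: Chemical-Protein Interaction Extraction with Graph Convolutional
    Networks over Pruned Dependency Trees
Version: 0.1.0
Authors@R:
    person("cpigcn", "maintainers", email = "cpigcn@example.org",
           role = c("aut", "cre"))
Description: Sentence-level chemical-protein relation extraction in the
    ChemProt / BioCreative VI setting. Reads the tab-separated
    abstracts/entities/relations corpus format, builds sentence-level
    candidate chemical-gene pairs, ingests dependency parses from
    CoNLL-U, applies path-centric pruning of the dependency tree around
    the lowest common ancestor of the two entity mentions, and scores
    candidates with a bidirectional LSTM encoder followed by a
    degree-normalized graph convolutional network with self-loops,
    entity-aware max-pooling and a softmax classifier. Includes
    micro-averaged precision/recall/F evaluation, pruning-distance and
    feature-ablation sweeps, and a synthetic ChemProt-format corpus
    generator with plantable relation signal so the full pipeline is
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
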