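Package: temporalkg
Title: Bimodal Temporal Relation Extraction with Event Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts temporal relations (before, after, overlap) between
    event mentions in clinical-style text using a bimodal classifier that
    fuses a text branch (entity-marker token sequences, contextual
    embeddings, mean-pooled event vectors) with a graph branch (a
    relational graph convolution over an event-centric knowledge graph
    whose edges may carry probability vectors over relation types).
    Includes the full event-graph pipeline: concept consolidation via a
    dictionary or pass-through entity linker, inverse and transitive
    relation enrichment, k-hop subgraph slicing, confidence filtering,
    and three evaluation scenarios (gold graph, bootstrapped graph from
    the model's own predictions, oracle-filtered graph), plus a seeded
    generator of synthetic annotated corpora with latent event timelines
    for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
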