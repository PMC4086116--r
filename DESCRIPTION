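Package: mirrank
Title: Context-Based Joint Ranking of MicroRNAs and Their mRNA Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly prioritizes candidate microRNAs (miRs) and their mRNA
    targets by relevance to a biological context. Gene-set enrichment of a
    test gene list (hypergeometric tests with Bonferroni or
    Benjamini-Hochberg correction, run per annotation category) yields
    reciprocal-p significance scores for genes; scores are propagated
    across heterogeneous annotation categories to convergence and
    optionally fused with an interactome signal computed by HITS with
    priors rooted at a training gene set. miR scores are then the sum of
    their top-ranked targets' scores, with or without a training-set
    multiplier, and expression level and fold change can be folded in via
    a Euclidean vector norm. Includes a synthetic-corpus generator with
    planted signal and a decoy-spiking / leave-one-out validation harness
    with ROC/AUC summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
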