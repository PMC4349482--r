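Package: chemenrich
Title: Ontology-Based Enrichment Analysis for Small-Molecule Sets
Version: 0.1.0
Authors@R:
    person("chemenrich", "maintainers", email = "chemenrich@example.org",
           role = c("aut", "cre"))
Description: Over-representation analysis of small-molecule sets against a
    ChEBI-style chemical ontology. Parses OBO flat files into a typed
    directed graph, computes transitive annotation sets over the is_a,
    has_part and has_role relations, and tests each ontology class with
    either a plain binomial tail test or a weighted saddlepoint
    (Lugannani-Rice) tail approximation of accumulated weights against the
    empirical weight background. Results are corrected with the
    Benjamini-Hochberg false-discovery rate and compacted into an
    exportable result graph by a configurable pruning strategy
    (zero-degree, root-children, molecule-leaves, high-p-value-branch and
    linear-branch-collapse pruners applied in pre-loop, loop-to-fixpoint
    and final phases). Includes a synthetic ontology/sample generator and
    a command-line interface; exports tables (TSV) and networks (GraphML,
    SIF, node-link JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
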