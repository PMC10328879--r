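Package: pdspace
Title: Spaces of Phylogenetic Diversity Indices on Rooted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for apportioning the phylogenetic diversity (PD) of a rooted
    phylogenetic tree among its leaves. Represents any diversity index by its
    coefficient matrix, validates the descent and neutrality conditions, and
    provides the Fair Proportion (FP) and Equal-Splits (ES) indices as special
    cases. Supports the consistent (flow-based) form of an index via per-vertex
    ratios of allocation, and explores the convex space of all diversity indices
    on a tree: its dimension from tree-shape equivalence classes, its corner
    (extreme) indices, Caratheodory bases, per-leaf score bounds, and the
    edge-contraction continuity property that characterises the Fair Proportion
    index. Includes a Newick reader/writer, canonical tree-shape codes, worked
    example trees (including a hominoid phylogeny) and a seeded random tree
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    ape,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
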