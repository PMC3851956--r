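Package: crfalign
Title: Biological Network Querying and Alignment with Conditional Random Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Query a small protein-protein interaction network inside a
    large one, or align two networks one-to-one, by maximum a posteriori
    inference in a conditional random field whose node potentials carry
    sequence similarity and whose edge potentials reward conserved
    interactions.  Includes an iterative bi-directional mapping strategy
    that turns the many-to-one querying method into a symmetric one-to-one
    aligner, best-hit baselines, a gene-duplication network evolution
    simulator with known true alignments, and structural and biological
    evaluation measures (matching pairs, edge correctness, edge accumulated
    coverage, largest common connected subgraph, shared GO terms, GO
    coverage, pathway hits and coverage, ortholog pairs).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
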