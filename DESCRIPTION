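Package: rnamotifs
Title: Attributed Graph Representations, Motif Extraction and Similarity
    Analysis for RNA 3D Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds nucleotide-level attributed graphs of RNA 3D structures
    (covalent, Watson-Crick and non-Watson-Crick edges), extracts recurrent
    motifs (hairpin loops, internal loops, bulges, 3- to 8-way junctions) by
    attribute-constrained subgraph isomorphism accelerated by compression of
    unpaired-nucleotide runs into weighted super-edges, detects and classifies
    pseudoknots from extended dot-bracket notation into six topological types,
    catalogs motif occurrences with conformation classification over
    non-Watson-Crick decorations, scores motif-based RNA similarity with a
    Weisfeiler-Lehman graph kernel and optimal motif assignment, clusters RNAs
    by similarity, and models the evolution of pairwise similarity with a
    drift-diffusion (Fokker-Planck) equation. Includes a seeded synthetic
    structure generator with known motif inventories so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
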