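Package: hypermotifs
Title: Enrichment and Dynamics of Network Motif Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how small network motifs (feedforward loops,
    mutual feedback circuits, three-node loops) are assembled into higher-level
    modules in directed networks. Enumerates the topologically distinct ways two
    motifs can be joined by sharing nodes (combinations) or by cross-linking
    edges (interactions); detects statistically enriched motif combinations via
    role-overlap Jaccard statistics scored against a null ensemble that
    preserves degree sequences and the full three-node subgraph census; and
    simulates the emergent dynamics of motif assemblies with Hill-function
    ordinary differential equation models, including fixed-point analysis and
    oscillation / synchronization classification. A synthetic-network generator
    with planted motif combinations supports validation, and a neighborhood
    random-walk downsampler reduces large networks to analyzable subnetworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
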