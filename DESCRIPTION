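Package: propmash
Title: Signal Propagation in Protein Interaction Networks and
    Alignment-Free Phylogenomics
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two desk-scale comparative-genomics computations:
    (1) shell-wise signal-propagation analysis of protein-protein
    interaction networks (confidence-filtered STRING-style edge lists,
    hub degree ranking, breadth-first shell decomposition, the |D(r)|
    propagation profile with its expansion rate and saturation radius),
    and (2) alignment-free phylogenomics from k-mer MinHash sketches
    (Jaccard and Mash-style p-distances, neighbor joining with balanced
    minimum-evolution refinement, and quartet-based REQ branch support).
    Includes seeded synthetic-data generators (random graphs, a
    degree-constrained aerotolerance-operon network fixture, and genomes
    evolved along known trees) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
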