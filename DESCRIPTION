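Package: lpxevo
Title: Comparative Genomics of the Kdo2-Lipid A (Lpx/Waa) Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for tracing the evolution of the nine-enzyme
    Kdo2-lipid A biosynthesis pathway across bacterial proteomes: affine-gap
    Smith-Waterman search with constant-database-size E-values and
    reciprocal-best-hit orthology, profile hidden Markov model construction
    and calibrated search, variable-spacer motif scanning with the LpxH/LpxH2
    diagnostic-residue rule, progressive multiple alignment, neighbor-joining
    trees with bootstrap support and fixed-tree likelihood scoring, Dollo
    parsimony gain/loss inference, gene-tree/species-tree reconciliation,
    and max-gap gene-cluster plus gene-fusion detection. A synthetic-genome
    generator (species trees, duplication/loss histories, motif-bearing
    sequences, gene orders with planted clusters and fusions) provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
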