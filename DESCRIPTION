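Package: primereval
Title: Evaluating 16S rRNA Primers by the Information Content of Their Short Reads
Version: 0.1.0
Authors@R:
    person("primereval", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools to judge degenerate 16S rRNA gene primers by how much of the
    full-length gene's information their short sequencing reads preserve.
    Implements IUPAC degenerate in-silico PCR with coverage and non-coverage
    tables, unidirectional amplicon (short read) extraction from aligned
    libraries, neighbor-joining tree inference with bootstrap supports,
    patristic distance matrices, Robinson-Foulds and support-weighted
    Robinson-Foulds (WRF1/WRF2) topology metrics, branch-length comparison via
    Pearson correlation, through-origin slopes, binned resolving-power
    profiles, metric multidimensional scaling with Procrustes superposition
    (weighted RMSD), average-linkage OTU clustering with hard cutoffs, a
    Wang-style naive-Bayes k-mer taxonomic classifier with bootstrap
    confidence, a sliding-window phylogenetic placement surrogate, and a
    seeded simulator of 16S-like aligned libraries with conserved primer sites
    alternating with fast-evolving variable regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan,
    withr
Config/testthat/edition: 3
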