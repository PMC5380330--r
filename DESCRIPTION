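Package: cikmir
Title: miRNA Microarray Differential Expression, Genomic Clustering and
    Target-Network Analysis for Cytokine-Induced Killer Cells
Version: 0.1.0
Authors@R:
    person("CIK", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for miRNA microarray profiling of
    cytokine-induced killer (CIK) cells against peripheral blood
    mononuclear cells: quantile normalization, detection-flag-consistent
    differential expression screening (fold change and pooled-variance t
    tests), cross-contrast set comparison, genomic clustering of miRNA
    loci by inter-locus distance, gene-set over-representation analysis
    (Fisher's exact and chi-squared tests with Benjamini-Hochberg FDR),
    and bipartite miRNA-target network construction with Cytoscape
    compatible export.  Ships a synthetic-data generator with planted
    differential expression, planted genomic clusters and planted
    gene-set enrichment so that every stage is testable without raw
    array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
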