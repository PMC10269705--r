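Package: pgpan
Title: Habitat-Resolved Pan-Genome and Functional Profiling of Plant
    Growth-Promoting Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative functional genomics of
    plant growth-promoting bacteria across leaf-associated,
    soil-associated and other habitats. Provides genome quality
    filtering and ANI-based dereplication, cophenetic distances and a
    neighbor-joining tree builder, PAM k-medoids clustering with
    silhouette-based model selection, pan-genome partitioning into core,
    accessory and unit-specific gene families, phylogenetically matched
    subsampling, CAZyme family assignment by global-alignment identity
    with per-megabase normalisation, habitat enrichment statistics
    (Student's t, one-way ANOVA, PCA, phylogenetic PCA, PERMANOVA), and
    a synthetic-cohort generator with planted habitat structure so the
    whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    phytools,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
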