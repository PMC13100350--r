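Package: RegRatio
Title: Regulation Ratio Analysis of Transcriptional and Post-Transcriptional Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates chromatin-accessibility (ATAC-seq) peaks and RNA-protein
    occupancy (POP-seq) peaks at gene level to compute a per-gene Regulation
    Ratio: the density of significant POP-seq peaks in the gene body divided by
    the density of significant ATAC-seq peaks in a promoter-expanded gene
    window. Genes are classified as predominantly transcriptionally regulated,
    balanced, or predominantly post-transcriptionally regulated, and the
    package provides the downstream comparative machinery: nonparametric group
    statistics (Mann-Whitney U with exact small-sample p-values, Kruskal-Wallis,
    Cliff's delta, Bonferroni correction, median fold changes), transcript
    biotype enrichment with odds ratios, cross-sample classification agreement,
    GSEA pre-ranked list export, and a fully seeded synthetic-data generator
    for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, GeneRegulation, ATACSeq, Transcriptomics, StatisticalMethod
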