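Package: starrcall
Title: Activity Calling and Enrichment Analysis for AAV STARR-seq MPRAs
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of amplicon-based massively parallel reporter assays
    (MPRAs) in the STARR-seq orientation delivered by AAV, from raw amplicon
    count matrices to enhancer activity calls. Implements proportion
    normalization with inclusion filters, a GC-aware background regression
    model with Z-residual p-values and empirical tail-area FDR, a ratiometric
    RNA/DNA activity model with count stabilization, Wilcoxon rank-sum testing
    with Benjamini-Hochberg correction, background-aware permutation tests for
    enrichment of active amplicons in epigenomic annotation sets, and
    allele-level SNP count filtering and summaries. Includes a synthetic-data
    generator emulating the statistical structure of amplicon MPRA libraries
    (GC-correlated representation, basal transcription, replicate-specific
    dropout) with ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: FunctionalGenomics, GeneRegulation, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
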