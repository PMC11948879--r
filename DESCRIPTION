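Package: modfreqr
Title: Nucleotide Modification Frequency Tables and Haplotype-Aware
    Methylation Heatmaps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-sample and per-haplotype nucleotide-modification
    frequency tables from modified-base-tagged alignments (SAM/BAM MM and
    ML tags, with HP haplotype partitioning), nanopolish methylation-caller
    output, or precomputed tab-separated tables; stores them as block-gzip
    compressed, tabix-indexed files supporting fast region queries at
    cohort scale (hundreds of haplotype columns); and renders region
    heatmaps with an optional gene-annotation track and hierarchical
    clustering of samples using a missingness filter, position-weighted
    linear interpolation of missing values, and a deterministic dendrogram.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    parallel,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
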