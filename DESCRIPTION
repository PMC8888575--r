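Package: medipdmr
Title: Differential Methylation Regions from MeDIP-Seq Window Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide identification and biomarker evaluation of
    differential DNA methylation regions (DMRs) from MeDIP-Seq
    case/control comparisons. Tiles the genome into fixed windows,
    counts aligned fragments, normalizes libraries by trimmed mean of
    M-values (TMM), estimates a common negative-binomial dispersion by
    conditional maximum likelihood, applies a two-sided conditional
    exact test per window with Benjamini-Hochberg FDR control, merges
    significant windows into DMRs with an edge-extension rule,
    characterizes DMRs by CpG density and nearby genes, compares DMR
    sets across cohorts by exact and extended overlap, and evaluates
    DMR sets as classifiers via PCA, hierarchical clustering, and
    shrinkage linear discriminant analysis. Includes a synthetic-data
    generator with planted DMRs so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
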