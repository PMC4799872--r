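Package: exonCNV
Title: Exon-Resolution Copy-Number Detection from Targeted-Panel Read Depth
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects single- and multi-exon deletions and duplications from
    per-interval mean read depth on targeted gene panels. Depth is converted
    to fractional coverage per sample, normalized against the per-target
    median of the sequencing batch (sex-aware on the X and Y chromosomes),
    and thresholded on the log2 copy ratio to produce contiguous CNV calls.
    Post-calling review flags recurrent cohort artifacts and low-quality
    calls, a mechanism-based rule set assigns a simplified three-tier
    clinical classification, and cohort summaries report per-gene and
    per-phenotype detection rates. A coverage simulator with CNV spike-ins
    provides ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
biocViews: CopyNumberVariation, Coverage, Genetics, Sequencing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
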