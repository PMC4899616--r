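Package: methdmr
Title: Bin-Based Differential Methylation Analysis for Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for whole-genome bisulfite sequencing differential
    methylation analysis in plants. Classifies cytosines into CG/CHG/CHH
    contexts from a reference genome, loads Bismark-style per-cytosine
    reports, applies a minimum-coverage filter, detects hypermethylated
    differentially methylated regions (hyper-DMRs) by Fisher's exact test
    on 50-bp bins with gap-based merging, computes interval-set overlap
    and hypergeometric enrichment statistics, classifies DMRs by genomic
    feature and builds gene-body methylation metaprofiles, and summarizes
    clone-based locus-specific bisulfite sequencing. Includes a synthetic
    methylome generator that plants hyper-DMRs with known coordinates so
    the whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
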