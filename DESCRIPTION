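Package: panmem
Title: Pangenome Short-Read Alignment with a Run-Length BWT Index
Version: 0.1.0
Authors@R:
    person("panmem", "developers", email = "panmem@example.org", role = c("aut", "cre"))
Description: Indexes a collection of haplotypes (built from a reference FASTA
    plus a phased VCF, or from a multi-FASTA) in a run-length compressed
    Burrows-Wheeler transform index (the r-index) augmented with suffix-array
    samples at run boundaries and a thresholds structure. Short reads are
    aligned by a seed-and-extend strategy: maximal exact match (MEM) seeds are
    found via two-pass matching statistics, chained colinearly, gap-filled by
    affine dynamic programming, paired with insert-size aware mate selection
    and orphan recovery, lifted to linear-reference coordinates through
    variant-derived segment maps, and assigned BWA-style mapping qualities.
    A prefix-free parsing front-end, a synthetic pangenome and Illumina-like
    read simulator with ground-truth scoring, and a two-command CLI are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
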