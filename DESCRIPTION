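Package: isoscan
Title: Terminal-Exon Isoform Quantification from Paired-End RNA-Seq
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resolves a gene's 3'-terminal transcript variants from
    paired-end RNA-seq alignments. Counts reads on exon variants, counts
    exon-spanning mate pairs as isoform-specific evidence, normalizes
    counts across a cohort with quantile outlier removal, computes
    per-sample isoform ratios and their correlation structure, infers the
    3'UTR end from coverage drop-off across candidate terminal-exon
    endpoints, and makes rule-based transcript-variant presence calls.
    Includes a seeded splice-aware paired-end read simulator and a
    BRAF-like gene-model fixture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, AlternativeSplicing, RNASeq, Coverage
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'gene-model.R'
    'braf-fixture.R'
    'simulate.R'
    'read-counting.R'
    'junction-spanning.R'
    'expectation.R'
    'normalize.R'
    'inference.R'
    'pipeline.R'
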