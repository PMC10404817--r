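Package: brainReg
Title: Cross-Species Discovery of Primate-Specific Brain-Biased Genes and
    Their Candidate Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for identifying lineage-specific
    brain-biased genes across species and linking them to candidate
    regulatory elements. Provides brain-versus-nonbrain differential
    expression per species (median-of-ratios normalization, covariate
    screening, Welch-style inference on log-normalized counts), a
    decision-tree selection of primate-specific brain-biased genes with a
    fetal-zone expression filter, cross-species epigenetic peak
    classification through block coordinate maps, promoter-anchored
    chromatin-loop assignment of elements to genes, hypergeometric
    gene-set overlap testing with Benjamini-Hochberg correction,
    per-cluster cross-species single-cell differential expression, and a
    fully deterministic synthetic-data generator with planted ground
    truth for end-to-end validation.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
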