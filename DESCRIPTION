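Package: methylCOO
Title: Cell-of-Origin Methylome Modeling from DNA Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers, for each tumor sample, the differentiation stage and
    virtual methylome of its normal cell-of-origin from a reference
    differentiation continuum profiled on a DNA methylation array.
    Differentiation-dynamic CpGs are selected by effect size and t-test,
    a minimum-evolution phylogeny of the reference subpopulations built
    from Manhattan distances defines a linear differentiation axis,
    per-CpG linear models of beta values on differentiation stage predict
    the cell-of-origin methylome of each tumor, and CpGs deviating from
    that prediction in most patients are classified into four
    disease-specific classes (loss/gain at dynamic or stable sites).
    Downstream utilities link called CpGs to transcripts via promoter and
    enhancer assignment with methylation-expression correlation, and test
    region-set enrichment against the array background. A seeded
    synthetic-data generator emulates the full data structure so every
    stage is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
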