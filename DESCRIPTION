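Package: gestmeth
Title: Integrated RRBS Methylome and RNA-Seq Analysis of Placental Gestation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for reduced representation bisulfite sequencing
    (RRBS) DNA methylation and RNA-seq gene expression across placental
    gestational ages. Provides coverage-file import and depth/coverage
    filtering of CpG calls, gap-based merging of CpGs into regions,
    strand-aware promoter and gene-body annotation with CpG-island context,
    exact small-sample statistics (two-sided Mann-Whitney U by enumeration,
    Benjamini-Hochberg adjustment, exact two-sided binomial test), regional
    differential-methylation calling, RPKM-based differential expression with
    a group-average floor, binned methylation-expression correlation curves,
    sign-concordance analysis of doubly-significant genes, dual-luciferase
    normalization arithmetic, and a beta-binomial/negative-binomial synthetic
    data generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
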