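Package: methmut
Title: Methylation Dynamics and Germline CpG Mutability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of how DNA methylation dynamics across thirteen stages
    of human germline development (gametes, pre-implantation embryos and
    primordial germ cells) associate with germline CpG mutation rates, using
    rare population variants as a proxy for de novo mutation. Provides rare
    variant filtering and nine-way mutation-type classification from
    reference context, binomial methylation calling and level binning,
    dynamic methylation pattern enumeration and mutability ranking, per-site
    multiple linear regression of mutation state on stage methylation with
    stepwise selection, disjoint genomic region annotation with tiled
    weighted-methylation / C-to-T density correlations, promoter CpG
    observed/expected statistics correlated with tissue expression, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
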