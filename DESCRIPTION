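Package: rfinet
Title: Multi-Tissue Gene Co-Expression Networks and Feed-Efficiency
    Phenotypes for Cattle RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse multi-tissue RNA-seq experiments on sire
    groups divergent for residual feed intake (RFI). Implements RPKM
    normalisation with sample and expression filters, tissue-specificity
    calling by the two-thirds share rule, a crossed random-effects mixed
    model (REML variance components and BLUP gene-by-sire solutions) with
    a 2-SD differential-expression rule, regulatory impact factor (RIF)
    scoring of transcription factors, PCIT partial-correlation network
    inference with node-class annotation and network summaries, feedlot
    phenotype derivations (ADG, metabolic mid-weight, RFI, feed
    conversion ratio, feeding behaviour, carcass specific gravity), a
    negative-binomial power calculation for two-group differential
    expression, and a seeded synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
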