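Package: maizeMQTL
Title: Meta-QTL Analysis of Maize Stalk-Lodging Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for meta-QTL analysis of maize stalk-lodging
    traits. Curates heterogeneous QTL reports with formula-based imputation of
    missing confidence intervals and phenotypic variance explained, projects
    QTLs from study linkage maps onto a high-density reference map by
    homothetic (common-marker interval) scaling, clusters projected QTLs per
    chromosome with a Gaussian mixture model with known per-observation
    variances fitted by EM and selected over K by five information criteria,
    validates consensus loci against GWAS marker-trait associations within
    flanking physical windows, and scores candidate genes on four lines of
    evidence. Ships a seeded synthetic-data generator with exported ground
    truth so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer,
    GenomicRanges,
    withr
Config/testthat/edition: 3
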