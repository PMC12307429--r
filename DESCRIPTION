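Package: snpcore
Title: Core Collection Selection and SNP Fingerprinting from Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-variant-calling analysis of germplasm collections:
    GATK-style hard filtering and variant summaries from VCF, minor-allele
    frequency and missingness site filters on diploidized genotype dosage
    matrices, neighbor-joining trees with locus bootstrap and GRM-based
    principal components, per-locus genetic diversity indices with
    core-versus-reserve evaluation, greedy genotype-coverage core-collection
    selection, and genetic-algorithm selection of minimal discriminating SNP
    fingerprint panels. Includes a configurable two-subpopulation genotype
    simulator (Balding-Nichols drift model) so every stage can be exercised
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    vcfR,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
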