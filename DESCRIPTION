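Package: namgei
Title: Yield Stability and Genotype-by-Environment Interaction Mapping in
    Nested Association Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide analysis of grain-yield stability and
    genotype-by-environment interaction (GEI) in nested association mapping
    (NAM) populations. Provides parental-origin recoding of biallelic SNP
    genotypes into marker-by-family incidence matrices, genomic relationship
    matrices, kinship-adjusted multiparental mixed-model association scans
    with likelihood-ratio tests against a half-degree-of-freedom chi-square
    null, Finlay-Wilkinson joint-regression stability indices used as a GWAS
    phenotype, an AMMI-style meta-analysis of per-environment family allele
    effects with a rank-one multiplicative interaction term extracted by
    singular value decomposition, Ward clustering of environments, and a
    synthetic-data generator that emulates the structure of a large soybean
    NAM multi-environment yield trial.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
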