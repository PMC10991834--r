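Package: cismr
Title: Cis Mendelian Randomisation for Drug Targets from GWAS Summary Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-sample summary-data Mendelian randomisation restricted to a
    drug-target gene region. Provides instrument selection within a gene
    window (significance filtering and greedy LD clumping), winner's curse
    adjustment of exposure effects by the FDR inverse quantile transformation,
    allele harmonisation with palindromic-variant resolution by allele
    frequency, Wald-ratio and fixed-effect inverse-variance-weighted
    estimation with Cochran's Q heterogeneity at the within-study and
    across-study pooling levels, and a GWAS summary-statistics simulator for
    calibration studies. The reference analysis evaluates CRP-weighted IL-6
    signalling proxies from the IL6R gene region against pulmonary arterial
    hypertension risk across three case-control GWAS sources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
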