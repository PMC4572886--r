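Package: mrivw
Title: Two-Sample Mendelian Randomization with GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summary-statistic Mendelian randomization for binary disease
    outcomes: per-SNP Wald ratios combined by the fixed-effect
    inverse-variance weighted (IVW) estimator, reported as odds ratios per
    standard deviation of the genetically predicted exposure. Includes
    allele harmonization of instrument and outcome tables, genotype quality
    control filters, fixed-effect cross-cohort meta-analysis of per-SNP
    associations, Bonferroni-screened sensitivity reruns with leave-one-out
    diagnostics, unweighted genetic-score scans against a confounder trait
    panel, a fully deterministic individual-level simulator of two-sample
    case-control designs with known ground truth, and a config-driven
    pipeline that assembles publication-style report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
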