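Package: mrlink
Title: Two-Sample Bidirectional Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-sample bidirectional Mendelian randomization (MR)
    with GWAS summary statistics: reading and validating summary-statistic
    tables, instrument selection by p-value threshold and distance/LD-based
    clumping, exposure-outcome allele harmonization including palindromic-SNP
    resolution, per-SNP variance explained and F-statistic instrument-strength
    screening, causal-effect estimation by inverse-variance weighting,
    MR-Egger regression and the weighted median, and a sensitivity battery
    (Egger intercept pleiotropy test, Cochran's Q heterogeneity, MR-PRESSO
    outlier resampling, leave-one-out influence). A seeded generator of
    synthetic two-sample summary statistics with known causal structure
    supports parameter-recovery, calibration and power studies without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
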