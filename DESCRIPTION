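Package: qadapt
Title: Quasi-Adaptive SNP-Specific Thresholds for Multiple Independent
    GWAS Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects multiple independent association signals within known
    GWAS loci using SNP-specific significance thresholds derived from
    LD- and distance-based weights plugged into a weighted Sidak
    correction, applied over iterative rounds of approximate conditional
    analysis from summary statistics and an LD reference panel. Includes
    locus construction and merging, allele harmonization, COJO-style
    conditional and joint estimation, an individual-level OLS replication
    procedure with per-category Bonferroni thresholds, Wakefield
    approximate-Bayes-factor colocalization of conditional or
    unconditional GWAS associations with cis-eQTLs, and a simulator for
    LD-blocked genotypes, multi-signal phenotypes and expression traits
    used for family-wise error rate and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
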