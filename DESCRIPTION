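Package: mrcoco
Title: Transcriptome-Wide Mendelian Randomisation with Pairwise
    Conditional Colocalisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening gene-expression exposures against disease
    outcomes using two-sample Mendelian randomisation on summary statistics:
    cis-instrument selection (p-value thresholding, LD clumping, F-statistic
    and Steiger direction filters), single-SNP Wald-ratio estimation with
    delta-method standard errors and Benjamini-Hochberg false-discovery
    control, Bayesian colocalisation via Wakefield approximate Bayes factors
    with pairwise conditional decomposition of multi-signal regions
    (summary-statistics conditional and joint analysis against an LD
    reference), and a multi-tissue eQTL lookup with LD-proxy substitution.
    Includes a synthetic summary-statistics generator (Markov haplotype
    panels, quantitative and case-control GWAS under known causal
    configurations) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
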