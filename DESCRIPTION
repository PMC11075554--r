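Package: gwasfunnel
Title: GWAS-to-Drug-Repurposing Candidate Funnel with Assay Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes drug-repurposing candidates from GWAS summary
    statistics by filtering associations on significance, annotating
    variants against gene models, intersecting with central-nervous-system
    eQTLs, inferring the required pharmacological mechanism (inhibitor or
    activator) from the concordance of risk-allele odds ratios with eQTL
    direction of effect, and filtering on approved drug-gene interactions
    and model-organism orthologs. Includes the characterization statistics
    used to describe such a reanalysis (control-SNP sampling, two-proportion
    chi-square, mean comparisons, gene-set overlap) and the time-to-event
    and rank statistics used for functional validation assays
    (Kaplan-Meier paralysis curves, log-rank, Mann-Whitney U,
    Kruskal-Wallis, fold changes), together with a synthetic-data generator
    that plants ground-truth candidates for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
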