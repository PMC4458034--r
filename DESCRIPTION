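Package: recurcna
Title: Copy-Number and Allelic-Ratio Analysis of Tumor Recurrence Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide SNP-array copy-number and allelic-ratio
    analysis of matched tumor/normal cohorts with recurrence outcomes.
    Simulates probe-level tumor/normal array data, matched patient cohorts
    with survival endpoints, qPCR Ct plates and literature frequency tables;
    preprocesses (quality control, genotype calling, normalization,
    de-waving), segments and calls copy-number states and allelic classes
    (retention, imbalance, loss of heterozygosity); tests group association
    hierarchically (genome, arm, region) with a permutation score test and
    Benjamini-Hochberg correction; summarises per-chromosome allelic status
    and compares groups with an exact r x c Fisher test; fits Cox
    proportional-hazards models for marker effects; implements qPCR
    molecule-counting allelic-ratio validation and a cross-study
    alteration-frequency counting rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    survival,
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
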