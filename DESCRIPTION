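Package: vafscreen
Title: Screening Low-Frequency Somatic and Germline Variants from Deep Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies variant allele fractions at candidate loci from deep
    amplicon read counts, derives a control-based outlier cut-off (mean plus
    three standard deviations, after Westgard quality-control rules), classifies
    somatic and germline carriers, tests case-control association with a
    two-tailed Fisher exact test implemented by hypergeometric enumeration,
    computes family-deduplicated allele frequencies, annotates variants on a
    minus-strand gene (genomic, cDNA, protein and 3'-UTR naming), scans 3'-UTRs
    for AU-rich elements, and compares clinical covariates between carrier
    groups. Ships a synthetic-cohort generator so the whole screening pipeline
    is testable without patient-level sequencing data.
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
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
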