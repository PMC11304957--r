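Package: caaxscreen
Title: Enrichment Analysis of Saturation CXXX Prenylation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing saturation CXXX-library selection screens of
    CaaX-type prenyltransferase specificity. Simulates a thermotolerance
    selection screen over the complete 8,000-member C-fixed tetrapeptide
    library, counts variants from amplicon FASTQ reads, computes
    replicate-aggregated frequencies and enrichment scores (NGS E-Scores),
    performs position-frequency-matrix (sequence logo) analysis of enriched
    and de-enriched subsets, provides coupon-collector library-coverage
    calculations, and cross-references colony-based screen hits against the
    enrichment scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
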