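Package: negsel
Title: Detecting Essential Cancer Proteins Under Negative Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for detecting "essential" cancer proteins:
    protein-coding genes under purifying (negative) selection in tumor
    somatic mutation data. Per-gene dN/dS ratios are estimated from somatic
    single-nucleotide variants with Nei-Gojobori (1986) expected-site
    counting, genes are filtered on variant support, a data-driven dN/dS
    threshold, tumor expression, and depletion of high-functional-impact
    variants relative to germline polymorphism data (f_germline > f_somatic).
    Includes hypergeometric gene-set over-representation with
    Benjamini-Hochberg correction, interaction-network summaries, and a
    fully controlled synthetic-cohort simulator with planted essential
    genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
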