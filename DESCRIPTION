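Package: rccpanel
Title: Blood Biomarker Candidate Screening for Clear Cell Renal Cell
    Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening tumor-overexpressed genes as candidate
    blood biomarkers in clear cell renal cell carcinoma (ccRCC).
    Implements tumor-versus-normal expression screening on RPKM matrices
    with two bespoke distribution-distance statistics (a 5th/95th
    percentile ratio and a two-sample overlap score), a blood-absence
    threshold cascade over pooled GEO-style and GTEx-style baseline
    sources, tissue-specificity gene-set subtraction, and the downstream
    RT-qPCR relative-quantification stage (detectability filtering,
    reference-gene delta-Cq normalization, relative quantities, signed
    fold changes and Mann-Whitney group verdicts). Seeded synthetic
    cohort generators with planted effects make every stage testable
    without external downloads; curated screening-panel fixtures are
    included.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
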