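Package: gliosplice
Title: Alternative-Splicing Disruption and PRMT5-Inhibitor Response in
    Glioblastoma Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit linking alternative-splicing disruption to
    PRMT5-inhibitor sensitivity in patient-derived glioblastoma stem cell
    (GSC) lines. Implements significance filtering and cross-sample
    consolidation of alternative splicing events (ASEs) by reciprocal
    coordinate overlap, predicted protein-impact classification,
    percent-spliced-in (PSI) quantification from capillary-electrophoresis
    amplicon tables, dose-response scoring (area above the curve, Hill EC50)
    with responder labelling, derivation of a baseline splicing-response
    signature, hypergeometric gene-set depletion enrichment with bootstrap
    standard errors, the signed GSEA gene-ranking statistic, and single-hit
    limiting-dilution analysis of sphere-forming frequency. A synthetic-data
    module generates every input shape with planted ground truth so the full
    pipeline is testable without controlled-access data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
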