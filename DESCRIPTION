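Package: melanoliq
Title: Multi-Analyte Liquid-Biopsy Scoring for Metastatic Melanoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying tumor-derived material in blood:
    chromosome-arm aneuploidy scoring of cell-free DNA (arm z-scores against a
    healthy-donor reference panel), genome-wide and melanoma-specific
    methylation scoring of methylation-dependent restriction-enzyme sequencing
    counts (moderated-t differential methylation, squared z-score summaries,
    donor-derived cutoffs), Poisson-corrected droplet digital PCR variant
    allele fractions, circulating tumor cell enumeration and leukapheresis
    recovery bookkeeping, and the cohort statistics that relate these assays
    to clinical parameters, including exhaustive-search Simon two-stage
    phase-II designs. A seeded synthetic-cohort generator reproduces the
    joint statistical structure these analyses assume so that every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    yaml
Config/testthat/edition: 3
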