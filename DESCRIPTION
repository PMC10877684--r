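Package: tcrtrack
Title: Clonal Tracking of TCR-Beta Repertoires Between Blood and Adipose Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired peripheral-blood (PB) and visceral adipose
    tissue (VAT) TCR-beta CDR3 clonotype repertoires. Reads AIRR Rearrangement
    and MiXCR-style clonotype tables, removes non-functional clonotypes,
    computes Shannon diversity and V-gene usage, identifies public clonotypes
    and tests group divergence of shared clones with Fisher's exact test,
    tracks recirculating clones (clonotypes present in both PB and VAT of the
    same individual) with per-clone expansion directionality, clusters CDR3
    sequences by central-region motifs with the standard four-criterion
    pattern-retention filter, annotates clonotypes against a VDJdb-style
    antigen database, and screens gene expression for correlation with
    HOMA-IR. A seeded synthetic-cohort generator with known ground truth makes
    every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
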