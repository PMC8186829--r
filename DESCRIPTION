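Package: intraclone
Title: Intraclonal IGHV-IGHD-IGHJ Diversification Analysis for CLL Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies post-transformation intraclonal diversification of the
    IGHV-IGHD-IGHJ rearrangement in chronic lymphocytic leukemia from
    UMI-tagged AIRR-style repertoire tables. Groups rearrangements into clonal
    families, identifies the clinically dominant clone (CDC) and its
    subclones, derives a replicate-concordance sensitivity threshold for
    subclonal expansion, reconstructs mutation-nested lineage trees and
    classifies their complexity, attributes mutations to mechanistic sequence
    contexts (AID hotspots and coldspots, Pol-eta, APOBEC, aging and cancer
    signature contexts) with one-sided binomial enrichment tests, computes
    transition:transversion spectra, estimates antigen-selection strength on
    replacement versus silent mutations in CDRs and FRs, and associates
    lineage complexity with clinical course. A synthetic-repertoire generator
    with full ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    survival,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    withr
Config/testthat/edition: 3
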