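Package: crowdcid
Title: Crowdsourced Extraction of Chemical-Induced Disease Relations from
    Annotated Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting chemical-induced disease (CID) relations
    from concept-annotated PubMed abstracts with a crowdsourcing workflow.
    Reads and writes the PubTator dialect used by the BioCreative V
    chemical-disease relation task, post-processes named-entity output
    (acronym resolution, MeSH filtering), generates chemical-disease
    candidate pairs, auto-accepts lexical "-induced" pattern matches, routes
    the remaining pairs into sentence- or abstract-scoped judgment tasks,
    simulates a quality-gated worker pool, aggregates judgments by threshold
    voting, and scores predictions with micro-averaged precision/recall/F,
    an NER-error filter, ROC analysis over vote thresholds, and multi-system
    overlap partitioning.  A synthetic-corpus generator with planted ground
    truth exercises every branch of the workflow at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
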