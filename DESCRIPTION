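Package: phenocurator
Title: Curate, Validate, and Summarize GA4GH Phenopacket Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building corpora of GA4GH phenopackets from tabular
    case-report curation templates, validating them against ontology-aware
    quality-control rules (identifier conventions, diagnosis cross-references,
    Human Phenotype Ontology consistency), and computing gene-cohort summary
    statistics. Includes a minimal obographs ontology loader with subsumption
    queries, canonical JSON serialization of phenopackets (one individual per
    file), a seeded synthetic-corpus generator with planted ground truth and
    fault injection for testing validators, and a command-line interface for
    the curator workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
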