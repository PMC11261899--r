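Package: qctags
Title: Standardized Quality-Control Contextual-Data Tags for Pathogen Sequence Submissions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for annotating pathogen sequence datasets with the PHA4GE
    standardized quality-control contextual-data tags. Provides an
    ontology-backed registry of the GenEpiO controlled vocabulary (fields,
    determinations, issues) with bidirectional label/CURIE resolution and
    extension-term registration; a QC-record data model with a rule-based
    validator encoding the community best practices (method-name requirement,
    semicolon multi-value dialect, ISO 8601 / semantic-versioning checks,
    name-version ordering, picklist membership, synthetic-construct metadata
    isolation); adapters that translate common QC-tool outputs (ncov-tools,
    FastQC, Kraken2, samtools depth, Quast, Nextclade, VADR, PHoeNIx,
    taxonomic-consensus calls) into standardized tag records; readers and
    writers for SRA user-defined attribute tables, ENA experiment-attribute
    XML fragments and a canonical JSON interchange form; and seeded synthetic
    fixture generators plus determination-breakdown summaries for
    GenomeTrakr-style reporting.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
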