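# Repository submission artifacts: SRA user-defined attribute tables
# (tab-separated) and ENA experiment-attribute XML fragments. Writers are
# bit-stable: fixed column order (five QC columns in standard order, then
# specimen fields, then extras first-seen), no timestamps.

#' Write a collection as an SRA user-defined attribute table
#'
#' Emits a tab-separated table whose header uses the snake_case attribute
#' names (`quality_control_method_name`, ...); term cells carry
#' `"label [CURIE]"` strings joined with `"; "`, empty fields are empty
#' cells. The collection must validate without errors first — the writer
#' refuses otherwise, attaching the validation report.
#'
#' @param collection A [qc_collection()].
#' @param path Optional file path; when `NULL` the table is returned as a
#'   single string.
#' @param registry Registry used for validation.
#' @param labels Label rendering passed to [render_record()].
#' @return The table text, invisibly when written to `path`.
#' @export
write_sra_table <- function(collection, path = NULL,
                            registry = qc_term_registry(),
                            labels = "canonical") {
  vset <- validate_collection(collection, registry = registry, profile = "lenient")
  if (!all(vset$passed)) {
    abort_qc(sprintf("Collection fails validation (record(s) %s); fix before writing.",
                     paste(which(!vset$passed), collapse = ", ")),
             class = "qctags_validation_refusal", report = vset)
  }
  tbl <- collection_to_table(
    qc_collection(collection$records, dialect = "sra_snake"), labels = labels)
  cells <- c(names(tbl), unlist(lapply(seq_len(nrow(tbl)), function(i) unlist(tbl[i, ]))))
  if (any(grepl("[\t\n\r]", cells))) {
    abort_qc("Values must not contain tabs or newlines; clean the offending cells instead of relying on escaping.",
             class = "qctags_invalid_record")
  }
  lines <- c(paste(names(tbl), collapse = "\t"),
             vapply(seq_len(nrow(tbl)),
                    function(i) paste(unlist(tbl[i, ]), collapse = "\t"),
                    character(1)))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  readr::write_file(text, path)
  invisible(text)
}

#' Read an SRA user-defined attribute table
#'
#' First row is the header. QC columns parse into records leniently (a
#' per-row validation report is attached as attribute `validation`);
#' non-QC columns — among them the companion contextual-data attributes
#' (`amplicon_PCR_primer_scheme`, `amplicon_size`, `dehosting_method`,
#' `sequence_submitter_contact_email`) — are preserved verbatim in each
#' record's extras.
#'
#' @param text File path or table text.
#' @param registry A [qc_term_registry()].
#' @return A [qc_collection()] with attribute `validation`
#'   (a `qc_validation_set`).
#' @export
read_sra_table <- function(text, registry = qc_term_registry()) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readr::read_file(text)
  }
  if (!nzchar(str_trim(text))) {
    abort_qc("Missing header: empty table.", class = "qctags_format_error")
  }
  tbl <- readr::read_tsv(I(text), col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  records <- lapply(seq_len(nrow(tbl)), function(i) {
    parse_record(tbl[i, ], registry = registry, dialect = "sra_snake",
                 mode = "lenient")
  })
  collection <- qc_collection(records, dialect = "sra_snake")
  attr(collection, "validation") <-
    validate_collection(collection, registry = registry, profile = "lenient")
  collection
}

#' Write a record as ENA experiment attributes
#'
#' Emits one `EXPERIMENT_ATTRIBUTE` element per populated field inside an
#' `EXPERIMENT_ATTRIBUTES` wrapper, with `TAG` the snake_case attribute
#' name and `VALUE` the rendered cell, in the standard field order. This is
#' the user-defined-attribute fragment included in ENA experiment metadata;
#' full ENA EXPERIMENT-set schema coverage is out of scope.
#'
#' @param record A `qc_record`; must validate without errors.
#' @param registry Registry used for validation.
#' @return XML fragment text.
#' @export
write_ena_experiment_attributes <- function(record, registry = qc_term_registry()) {
  report <- validate_record(record, registry = registry, profile = "lenient")
  if (!report_passed(report)) {
    abort_qc("Record fails validation; fix before writing.",
             class = "qctags_validation_refusal", report = report)
  }
  fields <- render_record(record, dialect = "sra_snake")
  root <- xml2::xml_new_root("EXPERIMENT_ATTRIBUTES")
  for (nm in names(fields)) {
    attr_node <- xml2::xml_add_child(root, "EXPERIMENT_ATTRIBUTE")
    xml2::xml_add_child(attr_node, "TAG", nm)
    xml2::xml_add_child(attr_node, "VALUE", fields[[nm]])
  }
  as.character(root)
}

#' Read ENA experiment attributes back into a record
#'
#' Inverse of [write_ena_experiment_attributes()] on its image.
#'
#' @param text XML fragment text.
#' @param registry A [qc_term_registry()].
#' @param mode Parse mode passed to [parse_record()].
#' @return A `qc_record`.
#' @export
read_ena_experiment_attributes <- function(text, registry = qc_term_registry(),
                                           mode = "lenient") {
  doc <- tryCatch(xml2::read_xml(text), error = function(e) {
    abort_qc(sprintf("Malformed XML fragment: %s", conditionMessage(e)),
             class = "qctags_parse_error")
  })
  attrs <- xml2::xml_find_all(doc, ".//EXPERIMENT_ATTRIBUTE")
  tags <- vapply(attrs, function(a) xml2::xml_text(xml2::xml_find_first(a, "./TAG")),
                 character(1))
  vals <- vapply(attrs, function(a) xml2::xml_text(xml2::xml_find_first(a, "./VALUE")),
                 character(1))
  parse_record(stats::setNames(vals, tags), registry = registry,
               dialect = "sra_snake", mode = mode)
}

#' Generate a submission template
#'
#' Writes the text analogue of the drop-down SRA submission form: a
#' header-only TSV with the QC attribute columns, plus a machine-readable
#' picklist sidecar (one row per allowed value per enumerated field).
#'
#' @param dir Output directory (created if needed).
#' @param registry A [qc_term_registry()]; extension terms appear in the
#'   picklists.
#' @return Invisibly, the paths written (`template`, `picklists`).
#' @export
write_submission_template <- function(dir, registry = qc_term_registry()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmap <- qc_field_dialect("sra_snake")
  template <- file.path(dir, "sra_submission_template.tsv")
  readr::write_file(paste0(paste(unname(fmap), collapse = "\t"), "\n"), template)

  pick_cat <- c(determination = "determination", issues = "issue",
                specimen_role = "misc")
  rows <- dplyr::bind_rows(lapply(names(pick_cat), function(fid) {
    terms <- registry[registry$category == pick_cat[[fid]], ]
    tibble::tibble(attribute = fmap[[fid]],
                   value = vapply(seq_len(nrow(terms)),
                                  function(i) render_term(terms[i, ]), character(1)))
  }))
  picklists <- file.path(dir, "sra_picklists.tsv")
  readr::write_file(paste0(paste(c("attribute\tvalue",
                                   paste(rows$attribute, rows$value, sep = "\t")),
                                 collapse = "\n"), "\n"), picklists)
  invisible(c(template = template, picklists = picklists))
}
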