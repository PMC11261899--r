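#' Render a QC record as a field-name → value map
#'
#' Term values render as `"label [CURIE]"` joined with `"; "`; method
#' versions render positionally aligned with method names (a missing version
#' in the middle of a list renders as an empty segment to preserve
#' alignment). Absent fields are omitted from the map; passthrough extras
#' are appended verbatim.
#'
#' @param record A `qc_record`.
#' @param dialect Field-name dialect (see [qc_field_dialect()]).
#' @param labels `"canonical"` renders registry labels; `"as_given"`
#'   reproduces the spelling the value arrived with (synonyms, case).
#' @param include_extras Append passthrough fields to the map.
#' @return Named character vector (empty for an empty record).
#' @export
render_record <- function(record, dialect = c("sra_snake", "display"),
                          labels = c("canonical", "as_given"),
                          include_extras = TRUE) {
  if (is.character(dialect) && length(dialect) == 1 && !dialect %in% c("sra_snake", "display")) {
    abort_qc(sprintf("Unknown dialect '%s'.", dialect), class = "qctags_invalid_record")
  }
  dialect <- match.arg(dialect)
  labels <- match.arg(labels)
  fmap <- qc_field_dialect(dialect)

  render_terms <- function(terms) {
    if (nrow(terms) == 0) return(NULL)
    toks <- vapply(seq_len(nrow(terms)), function(i) {
      t <- terms[i, ]
      lab <- if (labels == "as_given") t$raw else if (t$resolved) t$label else t$raw
      if (!is.na(t$curie)) sprintf("%s [%s]", lab, t$curie) else lab
    }, character(1))
    paste(toks, collapse = MULTIVALUE_SEP)
  }

  out <- character()
  m <- record$methods
  if (nrow(m) > 0 && any(!is.na(m$name))) {
    out[fmap[["method_name"]]] <- paste(m$name[!is.na(m$name)], collapse = MULTIVALUE_SEP)
  }
  if (record$n_versions > 0 || any(!is.na(m$version))) {
    vs <- m$version
    if (nrow(m) == 0) vs <- character()
    if (any(!is.na(vs))) {
      out[fmap[["method_version"]]] <-
        paste(ifelse(is.na(vs), "", vs), collapse = MULTIVALUE_SEP)
    }
  }
  d <- render_terms(record$determinations)
  if (!is.null(d)) out[fmap[["determination"]]] <- d
  i <- render_terms(record$issues)
  if (!is.null(i)) out[fmap[["issues"]]] <- i
  if (!is.null(record$details)) out[fmap[["details"]]] <- record$details
  r <- render_terms(record$specimen_role)
  if (!is.null(r)) out[fmap[["specimen_role"]]] <- r
  if (!is.null(record$specimen_details)) {
    out[fmap[["specimen_details"]]] <- record$specimen_details
  }
  if (include_extras && length(record$extras) > 0) {
    out[names(record$extras)] <- unname(record$extras)
  }
  out
}

#' Parse a field-name → value map into a QC record
#'
#' Inverse of [render_record()] on its image. Field names are matched
#' against the dialect case-insensitively; unrecognized names are preserved
#' in the record's `extras`, among them companion contextual-data attributes
#' (`amplicon_PCR_primer_scheme`, `dehosting_method`, ...). Multi-value
#' cells are split on semicolons (commas accepted in lenient mode); details
#' fields are atomic and never split. Versions are split positionally,
#' keeping empty segments aligned with their method names.
#'
#' @param fields Named character vector or single-row data frame.
#' @param registry A [qc_term_registry()].
#' @param dialect Field-name dialect (see [qc_field_dialect()]).
#' @param mode `"strict"` errors on unresolvable tokens; `"lenient"` keeps
#'   them verbatim and defers to [validate_record()].
#' @return A `qc_record`.
#' @export
parse_record <- function(fields, registry, dialect = c("sra_snake", "display"),
                         mode = c("lenient", "strict")) {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (is.data.frame(fields)) {
    stopifnot(nrow(fields) == 1)
    fields <- stats::setNames(as.character(unlist(fields[1, ])), names(fields))
  }
  fmap <- qc_field_dialect(dialect)
  lookup <- stats::setNames(names(fmap), tolower(fmap))

  blank <- function(x) is.null(x) || is.na(x) || !nzchar(str_trim(x))
  vals <- stats::setNames(vector("list", length(QC_FIELD_IDS)), QC_FIELD_IDS)
  extras <- character()
  for (nm in names(fields)) {
    id <- unname(lookup[tolower(nm)])
    if (is.na(id)) id <- NULL
    v <- fields[[nm]]
    if (is.null(id)) {
      if (!is.na(v)) extras[nm] <- v
    } else if (!blank(v)) {
      vals[[id]] <- v
    }
  }

  lenient <- mode == "lenient"
  methods <- parse_multivalue(vals$method_name %||% NA_character_, lenient = lenient)
  versions <- split_versions(vals$method_version %||% NA_character_, lenient = lenient)

  build_record(
    registry,
    methods = if (length(methods)) methods else NULL,
    versions = if (length(versions)) versions else NULL,
    determinations = parse_multivalue(vals$determination %||% NA_character_),
    issues = parse_multivalue(vals$issues %||% NA_character_),
    details = vals$details,
    specimen_role = vals$specimen_role,
    specimen_details = vals$specimen_details,
    extras = extras,
    mode = mode
  )
}

# Shared by as_tibble.qc_collection and write_sra_table: stable column
# order — five QC columns, two specimen columns, then extras first-seen.
collection_to_table <- function(collection, labels = "canonical") {
  fmap <- qc_field_dialect(collection$dialect)
  rows <- lapply(collection$records, render_record, dialect = collection$dialect,
                 labels = labels)
  extra_cols <- unique(unlist(lapply(rows, function(r) setdiff(names(r), fmap))))
  cols <- c(unname(fmap), extra_cols)
  tbl <- lapply(cols, function(cn) {
    vapply(rows, function(r) if (cn %in% names(r)) r[[cn]] else "", character(1))
  })
  names(tbl) <- cols
  tibble::as_tibble(tbl)
}
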