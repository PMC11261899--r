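# The QC record model: one sample's quality-control contextual-data
# annotation. Term-bearing fields hold resolved registry references
# (identifier-first); the raw as-written spelling is kept alongside so that
# synonym spellings can be reproduced on render.

term_tibble <- function(raw = character(), label = character(),
                        curie = character(), category = character(),
                        resolved = logical()) {
  tibble::tibble(raw = as.character(raw), label = as.character(label),
                 curie = as.character(curie), category = as.character(category),
                 resolved = as.logical(resolved))
}

# Resolve one token (label, synonym, CURIE, or "label [CURIE]") against the
# registry. Strict mode requires resolution within the expected category
# (Not Applicable is additionally legal in list fields); lenient mode
# resolves across categories and retains unresolved tokens for validation.
resolve_token <- function(registry, token, category, mode = "strict",
                          field = NULL, allow_na_term = TRUE) {
  tok <- parse_term_string(token)
  hit <- NULL
  if (!is.na(tok$curie)) {
    hit <- tryCatch(resolve_curie(registry, tok$curie), qctags_error = function(e) NULL)
  } else {
    hit <- tryCatch(resolve_label(registry, tok$label), qctags_error = function(e) NULL)
  }
  if (is.null(hit)) {
    if (mode == "strict") {
      abort_unknown_term(token, registry$label[registry$category %in% category],
                         field = field)
    }
    return(term_tibble(raw = tok$label %||% token,
                       label = tok$label %||% token,
                       curie = tok$curie, category = NA_character_,
                       resolved = FALSE))
  }
  ok_cat <- hit$category %in% category ||
    (allow_na_term && !is.na(hit$curie) && hit$curie == "GENEPIO:0001619")
  if (mode == "strict" && !ok_cat) {
    abort_qc(sprintf(
      "Term '%s' is a %s-category term and is not valid in field '%s' (use mode = \"lenient\" to record it as written).",
      hit$label, hit$category, field %||% category[1]),
      class = "qctags_category_mismatch", value = token)
  }
  raw_label <- tok$label
  if (is.na(raw_label)) raw_label <- hit$label  # CURIE-only input: restore label
  term_tibble(raw = raw_label, label = hit$label, curie = hit$curie,
              category = hit$category, resolved = TRUE)
}

resolve_tokens <- function(registry, tokens, category, mode, field) {
  if (length(tokens) == 0) return(term_tibble())
  dplyr::bind_rows(lapply(tokens, resolve_token, registry = registry,
                          category = category, mode = mode, field = field))
}

#' Build a QC record
#'
#' Constructs one sample's QC annotation from method names/versions,
#' determination and issue values (labels, synonyms, CURIEs, or
#' `"label [CURIE]"` strings), free-text details, and the optional
#' experimental-specimen fields used for synthetic lab constructs. All
#' term-bearing values are resolved against the registry; input order is
#' preserved everywhere.
#'
#' Construction is deliberately more permissive than validation: shapes that
#' violate best-practice rules (tags without a method name, version/name
#' count mismatch) construct fine and are reported by [validate_record()],
#' which is the enforcement point. `mode` gates only term resolution:
#' `"strict"` requires every value to resolve within its field's category
#' (`Not Applicable` is always legal in the list fields), `"lenient"`
#' accepts cross-category placement and retains unresolved tokens verbatim
#' for the validator to flag.
#'
#' @param registry A [qc_term_registry()].
#' @param methods Character vector of method names, or a list of
#'   `(name, version)` pairs, or a tibble with columns `name`, `version`.
#' @param versions Character vector of versions, positionally aligned with
#'   `methods` (only when `methods` is a character vector).
#' @param determinations,issues Character vectors of picklist values.
#' @param details,specimen_details Free text (atomic; never split).
#' @param specimen_role Picklist value, e.g. `"synthetic lab construct"`.
#' @param extras Named character vector of passthrough fields preserved
#'   verbatim (unrecognized columns, companion attributes).
#' @param mode `"strict"` or `"lenient"` (see Details).
#' @return A `qc_record` object.
#' @examples
#' reg <- qc_term_registry()
#' rec <- build_record(reg,
#'   methods = "ncov-tools", versions = "1.9.1",
#'   determinations = "sequence flagged for potential quality control issues",
#'   issues = "sequence contaminated",
#'   details = ">5 ambiguous sites in consensus")
#' render_record(rec)
#' @export
build_record <- function(registry, methods = NULL, versions = NULL,
                         determinations = NULL, issues = NULL, details = NULL,
                         specimen_role = NULL, specimen_details = NULL,
                         extras = NULL, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)

  if (is.null(methods)) {
    methods_tbl <- tibble::tibble(name = character(), version = character())
    n_versions <- length(versions %||% character())
    if (n_versions > 0) {
      methods_tbl <- tibble::tibble(name = NA_character_, version = as.character(versions))
    }
  } else if (is.data.frame(methods)) {
    methods_tbl <- tibble::tibble(name = as.character(methods$name),
                                  version = as.character(methods$version))
    n_versions <- if (all(is.na(methods_tbl$version))) 0L else nrow(methods_tbl)
  } else if (is.list(methods)) {
    methods_tbl <- tibble::tibble(
      name = map_chr(methods, function(m) as.character(m[[1]])),
      version = map_chr(methods, function(m) {
        v <- if (length(m) >= 2) m[[2]] else NA
        if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
      })
    )
    n_versions <- if (all(is.na(methods_tbl$version))) 0L else nrow(methods_tbl)
  } else {
    nm <- as.character(methods)
    vs <- as.character(versions %||% character())
    n_versions <- length(vs)
    pad <- function(x, n) { length(x) <- n; x }
    n <- max(length(nm), length(vs))
    methods_tbl <- tibble::tibble(name = pad(nm, n), version = pad(vs, n))
  }
  if (any(!is.na(methods_tbl$name) & !nzchar(str_trim(methods_tbl$name)))) {
    abort_qc("Method names must be non-empty.", class = "qctags_invalid_record")
  }

  norm_text <- function(x) {
    if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(str_trim(x))) NULL
    else as.character(x)
  }

  role <- term_tibble()
  if (!is.null(norm_text(specimen_role))) {
    role <- resolve_token(registry, specimen_role, category = "misc",
                          mode = mode, field = "experimental specimen role type")
  }
  extras <- extras %||% character()
  if (length(extras) > 0 && is.null(names(extras))) {
    abort_qc("`extras` must be named.", class = "qctags_invalid_record")
  }

  structure(list(
    methods = methods_tbl,
    n_versions = as.integer(n_versions),
    determinations = resolve_tokens(registry, determinations, "determination",
                                    mode, "quality control determination"),
    issues = resolve_tokens(registry, issues, "issue", mode,
                            "quality control issues"),
    details = norm_text(details),
    specimen_role = role,
    specimen_details = norm_text(specimen_details),
    extras = extras
  ), class = "qc_record")
}

#' @export
print.qc_record <- function(x, ...) {
  cat("<qc_record>\n")
  flds <- render_record(x, dialect = "display")
  for (nm in names(flds)) cat(sprintf("  %s: %s\n", nm, flds[[nm]]))
  if (length(x$extras)) {
    cat(sprintf("  + %d passthrough field(s): %s\n", length(x$extras),
                paste(names(x$extras), collapse = ", ")))
  }
  invisible(x)
}

# Identity key for a term reference: the CURIE when present (identifiers are
# ground truth), otherwise the case-folded label.
term_keys <- function(terms) {
  ifelse(!is.na(terms$curie), terms$curie, tolower(terms$label))
}

#' Compare two QC records for semantic equality
#'
#' Records are equal when the five QC fields and the two specimen fields
#' agree after term resolution: term lists are compared element-wise by
#' CURIE where available (so a record built from labels equals one built
#' from identifiers) and case-insensitively by label otherwise; methods and
#' versions compare positionally. Passthrough extras are not part of record
#' identity.
#'
#' @param a,b `qc_record` objects.
#' @return Logical scalar.
#' @export
record_equals <- function(a, b) {
  eq_chr <- function(x, y) {
    (is.null(x) && is.null(y)) || (!is.null(x) && !is.null(y) && identical(x, y))
  }
  eq_vec <- function(x, y) length(x) == length(y) && all(x == y | (is.na(x) & is.na(y)))
  eq_vec(a$methods$name, b$methods$name) &&
    eq_vec(a$methods$version, b$methods$version) &&
    eq_vec(term_keys(a$determinations), term_keys(b$determinations)) &&
    eq_vec(term_keys(a$issues), term_keys(b$issues)) &&
    eq_chr(a$details, b$details) &&
    eq_vec(term_keys(a$specimen_role), term_keys(b$specimen_role)) &&
    eq_chr(a$specimen_details, b$specimen_details)
}

#' Bundle QC records into a collection
#'
#' @param records List of `qc_record` objects.
#' @param dialect Field-name dialect the collection is keyed by when
#'   rendered to a table (see [qc_field_dialect()]).
#' @return A `qc_collection` object.
#' @export
qc_collection <- function(records = list(), dialect = c("sra_snake", "display")) {
  dialect <- match.arg(dialect)
  stopifnot(all(map_lgl(records, inherits, "qc_record")))
  structure(list(records = records, dialect = dialect), class = "qc_collection")
}

#' @export
length.qc_collection <- function(x) length(x$records)

#' @export
print.qc_collection <- function(x, ...) {
  cat(sprintf("<qc_collection: %d record(s), dialect '%s'>\n",
              length(x$records), x$dialect))
  invisible(x)
}

#' @describeIn qc_collection One row per record, rendered in the
#'   collection's field-name dialect; passthrough extras become columns in
#'   first-seen order.
#' @param x A `qc_collection`.
#' @param ... Unused.
#' @export
as_tibble.qc_collection <- function(x, ...) {
  collection_to_table(x)
}

#' @export
tidy.qc_record <- function(x, ...) {
  flds <- render_record(x, dialect = "display")
  tibble::tibble(field = names(flds), value = unname(unlist(flds)))
}

#' @export
glance.qc_record <- function(x, ...) {
  tibble::tibble(
    n_methods = nrow(x$methods),
    n_determinations = nrow(x$determinations),
    n_issues = nrow(x$issues),
    has_details = !is.null(x$details),
    synthetic = nrow(x$specimen_role) > 0 &&
      any(x$specimen_role$curie %in% "GENEPIO:0101039", na.rm = TRUE)
  )
}
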