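#' Canonical JSON interchange for QC record collections
#'
#' A documented, lossless JSON form for exchanging tagged collections
#' between systems. The document carries a `spec_version` string and a
#' `records` array; each term is encoded identifier-first as
#' `{"curie": ..., "label": ...}` (either key may be absent for CURIE-less
#' extensions or unresolved tokens). `from_canonical_json()` restores
#' canonical labels from the registry for CURIE-only terms, and the pair is
#' lossless: `from(to(x))` is record-equal to `x`.
#'
#' @param collection A [qc_collection()].
#' @param pretty Pretty-print the document.
#' @return `to_canonical_json()`: JSON text (UTF-8).
#' @export
to_canonical_json <- function(collection, pretty = FALSE) {
  enc_terms <- function(terms) {
    lapply(seq_len(nrow(terms)), function(i) {
      t <- terms[i, ]
      out <- list()
      if (!is.na(t$curie)) out$curie <- t$curie
      out$label <- if (t$resolved) t$label else t$raw
      out
    })
  }
  enc_record <- function(rec) {
    out <- list(
      methods = lapply(seq_len(nrow(rec$methods)), function(i) {
        m <- list(name = rec$methods$name[i])
        if (!is.na(rec$methods$version[i])) m$version <- rec$methods$version[i]
        m
      }),
      determinations = enc_terms(rec$determinations),
      issues = enc_terms(rec$issues)
    )
    if (!is.null(rec$details)) out$details <- rec$details
    if (nrow(rec$specimen_role) > 0) {
      out$specimen_role <- enc_terms(rec$specimen_role)[[1]]
    }
    if (!is.null(rec$specimen_details)) out$specimen_details <- rec$specimen_details
    if (length(rec$extras) > 0) out$extras <- as.list(rec$extras)
    out
  }
  doc <- list(
    spec_version = QCTAGS_SPEC_VERSION,
    dialect = collection$dialect,
    records = lapply(collection$records, enc_record)
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = pretty, null = "null")
}

#' @rdname to_canonical_json
#' @param text JSON document text (or a connection/file path accepted by
#'   [jsonlite::fromJSON()]).
#' @param registry A [qc_term_registry()] used to restore labels.
#' @param mode Term-resolution mode passed to [build_record()].
#' @return `from_canonical_json()`: a [qc_collection()].
#' @export
from_canonical_json <- function(text, registry, mode = "lenient") {
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      abort_qc(sprintf("Malformed canonical JSON document: %s", conditionMessage(e)),
               class = "qctags_parse_error")
    }
  )
  if (is.null(doc$records)) {
    abort_qc("Malformed canonical JSON document: missing 'records' at $.records.",
             class = "qctags_parse_error")
  }
  term_str <- function(t) {
    if (!is.null(t$curie) && is.null(t$label)) return(t$curie)
    if (!is.null(t$curie)) return(sprintf("%s [%s]", t$label, t$curie))
    t$label
  }
  records <- lapply(seq_along(doc$records), function(k) {
    r <- doc$records[[k]]
    tryCatch(
      build_record(
        registry,
        methods = if (length(r$methods)) {
          tibble::tibble(
            name = map_chr(r$methods, function(m) m$name %||% NA_character_),
            version = map_chr(r$methods, function(m) m$version %||% NA_character_)
          )
        } else NULL,
        determinations = vapply(r$determinations %||% list(), term_str, character(1)),
        issues = vapply(r$issues %||% list(), term_str, character(1)),
        details = r$details,
        specimen_role = if (!is.null(r$specimen_role)) term_str(r$specimen_role),
        specimen_details = r$specimen_details,
        extras = if (length(r$extras)) unlist(r$extras) else NULL,
        mode = mode
      ),
      qctags_error = function(e) {
        abort_qc(sprintf("At $.records[%d]: %s", k, conditionMessage(e)[1]),
                 class = "qctags_parse_error", parent = e)
      }
    )
  })
  qc_collection(records, dialect = (doc$dialect %||% "sra_snake"))
}
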