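#' Load the controlled-vocabulary term registry
#'
#' The registry holds every controlled-vocabulary entry of the PHA4GE
#' quality-control tag standard: the five QC fields and the two
#' experimental-specimen fields, the six determination values, the ten issue
#' values, and the two miscellaneous terms (`Not Applicable`, `synthetic lab
#' construct`). Core terms carry GenEpiO CURIEs (e.g. `GENEPIO:0100564`);
#' the two specimen fields have no published identifier and are registered
#' without one. Registered synonyms (e.g. `"sequenced contaminated"` for
#' `"sequence contaminated"`) resolve to the same term as the canonical
#' label. The vocabulary ships as a plain TSV under
#' `inst/extdata/qc_terms.tsv`, one row per term.
#'
#' @param path Optional path to an alternative registry TSV (columns
#'   `label`, `curie`, `category`, `synonyms` (pipe-separated), `provenance`).
#' @return A `qc_registry` object: a tibble of terms with columns `label`,
#'   `curie`, `category` (`field`, `determination`, `issue` or `misc`),
#'   `synonyms` (list column) and `provenance` (`core` or `extension`).
#' @examples
#' reg <- qc_term_registry()
#' resolve_label(reg, "sequence failed quality control")$curie
#' @export
qc_term_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "qc_terms.tsv", package = "qctags",
                                mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  terms <- tibble::tibble(
    label      = raw$label,
    curie      = ifelse(raw$curie == "", NA_character_,
                        vapply(raw$curie, function(x) if (x == "") NA_character_
                               else normalize_curie(x), character(1), USE.NAMES = FALSE)),
    category   = raw$category,
    synonyms   = lapply(strsplit(raw$synonyms, "|", fixed = TRUE),
                        function(s) s[nzchar(s)]),
    provenance = raw$provenance
  )
  new_qc_registry(terms)
}

new_qc_registry <- function(terms) {
  stopifnot(all(terms$category %in% c("field", "determination", "issue", "misc")))
  dup <- duplicated(paste(tolower(terms$label), terms$category))
  if (any(dup)) {
    abort_qc(sprintf("Duplicate label within category: %s",
                     paste(terms$label[dup], collapse = ", ")),
             class = "qctags_conflict")
  }
  curies <- terms$curie[!is.na(terms$curie)]
  if (anyDuplicated(curies)) {
    abort_qc("Duplicate CURIE in registry.", class = "qctags_conflict")
  }
  structure(terms, class = c("qc_registry", class(tibble::as_tibble(terms))))
}

#' @export
print.qc_registry <- function(x, ...) {
  cat(sprintf("<qc_registry: %d terms (%d core, %d extension)>\n",
              nrow(x), sum(x$provenance == "core"),
              sum(x$provenance == "extension")))
  NextMethod()
}

# CURIEs compare with an upper-case prefix and a zero-padded 7-digit local
# part, so "GENEPIO:1619" and "GENEPIO:0001619" are the same identifier.
normalize_curie <- function(curie) {
  m <- str_match(str_trim(curie), "^([A-Za-z][A-Za-z0-9_]*):([0-9]+)$")
  if (any(is.na(m[, 1]))) {
    abort_qc(sprintf("Not a CURIE (expected PREFIX:digits): '%s'",
                     curie[which(is.na(m[, 1]))[1]]),
             class = "qctags_malformed_token")
  }
  sprintf("%s:%07d", toupper(m[, 2]), as.integer(m[, 3]))
}

is_curie_shaped <- function(x) {
  str_detect(str_trim(x), "^[A-Za-z][A-Za-z0-9_]*:[0-9]+$")
}

#' Resolve a textual label (or synonym) to a registry term
#'
#' Lookup is case-insensitive over canonical labels and registered synonyms.
#' Identifiers are the ground truth of the standard; labels are the
#' human-facing surface, so label lookup always returns the full term with
#' its CURIE for identifier-first storage.
#'
#' @param registry A [qc_term_registry()] object.
#' @param label Label or synonym text; surrounding whitespace is ignored.
#' @param category Optional category (`"field"`, `"determination"`,
#'   `"issue"`, `"misc"`) restricting the search space.
#' @return One-row tibble for the matching term.
#' @export
resolve_label <- function(registry, label, category = NULL) {
  label <- str_trim(label)
  if (!nzchar(label)) {
    abort_qc("Empty label.", class = "qctags_unknown_term")
  }
  pool <- registry
  if (!is.null(category)) pool <- pool[pool$category %in% category, , drop = FALSE]
  needle <- tolower(label)
  hit <- tolower(pool$label) == needle |
    map_lgl(pool$synonyms, function(s) needle %in% tolower(s))
  if (!any(hit)) {
    abort_unknown_term(label, pool$label)
  }
  tibble::as_tibble(pool[which(hit)[1], , drop = FALSE])
}

#' Resolve a CURIE to a registry term
#'
#' The local part is zero-padded to seven digits before comparison, so
#' `GENEPIO:1619` resolves the same term as `GENEPIO:0001619`.
#'
#' @inheritParams resolve_label
#' @param curie Identifier shaped `PREFIX:digits`.
#' @return One-row tibble for the matching term.
#' @export
resolve_curie <- function(registry, curie) {
  curie <- normalize_curie(curie)
  hit <- !is.na(registry$curie) & registry$curie == curie
  if (!any(hit)) {
    abort_qc(sprintf("Unknown term: no registered term has identifier '%s'.", curie),
             class = "qctags_unknown_term", value = curie)
  }
  tibble::as_tibble(registry[which(hit)[1], , drop = FALSE])
}

#' Render a term as "label [CURIE]"
#'
#' Picklist values are exchanged as the textual label followed by the
#' ontology identifier in square brackets, e.g.
#' `"sequence failed quality control [GENEPIO:0100564]"`. Extension terms
#' registered without an identifier render as the bare label.
#'
#' @param term One-row term tibble (from [resolve_label()] etc.), or a plain
#'   list with `label` and `curie` entries.
#' @param label Optional label to print instead of the canonical one (used to
#'   preserve an as-written synonym spelling).
#' @return Character scalar.
#' @export
render_term <- function(term, label = NULL) {
  lab <- label %||% term$label[[1]]
  curie <- term$curie[[1]]
  if (is.null(curie) || is.na(curie)) lab else sprintf("%s [%s]", lab, curie)
}

#' Register a local extension term
#'
#' Deployments extend the picklists with initiative-specific vocabulary (the
#' GenomeTrakr network, for instance, reports a determination `"significant
#' quality control issues"` that is not in the core list). Extension terms
#' participate in every lookup and in validation exactly like core terms; a
#' CURIE-less extension renders as its bare label. Registration is
#' functional: the amended registry is returned, the input is not modified.
#'
#' @inheritParams resolve_label
#' @param label Canonical label for the new term.
#' @param category Term category.
#' @param curie Optional identifier (`PREFIX:digits`).
#' @param synonyms Optional character vector of synonyms.
#' @return The amended `qc_registry`.
#' @export
register_extension <- function(registry, label, category, curie = NULL,
                               synonyms = character()) {
  label <- str_trim(label)
  category <- match.arg(category, c("field", "determination", "issue", "misc"))
  taken <- tolower(c(registry$label[registry$category == category],
                     unlist(registry$synonyms[registry$category == category])))
  if (tolower(label) %in% taken) {
    abort_qc(sprintf("Conflict: '%s' is already registered in category '%s'.",
                     label, category),
             class = "qctags_conflict", value = label)
  }
  row <- tibble::tibble(
    label = label,
    curie = if (is.null(curie)) NA_character_ else normalize_curie(curie),
    category = category,
    synonyms = list(synonyms),
    provenance = "extension"
  )
  new_qc_registry(dplyr::bind_rows(tibble::as_tibble(registry), row))
}

#' The open method-name vocabulary
#'
#' Method names are deliberately unconstrained ("No prescribed values"):
#' any pipeline name or repository link is legal. This helper returns the
#' suggestion list of method names used across the standard's worked
#' examples plus the GenomeTrakr pipeline names, for autocomplete-style use
#' only — nothing validates against it.
#'
#' @return Character vector of suggested method names.
#' @export
qc_method_names <- function() {
  c("FastANI", "FastQC", "Kraken2", "Mash", "Nextclade", "ncov-tools",
    "PHoeNIx", "Quast", "samtools depth", "Samtools", "VADR",
    "GalaxyTrakr SSQuAWK", "CFSAN Wastewater Analysis Pipeline (C-WAP)")
}
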