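# Field-name dialects and the multi-value string dialect.
#
# Internal field ids are fixed; external spellings differ by venue:
# "display" uses the sentence-case field labels of the standard, "sra_snake"
# the snake_case attribute names used for SRA user-defined fields.

QC_FIELD_IDS <- c("method_name", "method_version", "determination", "issues",
                  "details", "specimen_role", "specimen_details")

FIELD_DIALECTS <- list(
  display = c(
    method_name      = "Quality control method name",
    method_version   = "Quality control method version",
    determination    = "Quality control determination",
    issues           = "Quality control issues",
    details          = "Quality control details",
    specimen_role    = "Experimental specimen role type",
    specimen_details = "Experimental specimen details"
  ),
  sra_snake = c(
    method_name      = "quality_control_method_name",
    method_version   = "quality_control_method_version",
    determination    = "quality_control_determination",
    issues           = "quality_control_issues",
    details          = "quality_control_details",
    specimen_role    = "experimental_specimen_role_type",
    specimen_details = "experimental_specimen_details"
  )
)

#' Field-name dialect lookup
#'
#' @param name `"display"` (sentence-case field labels) or `"sra_snake"`
#'   (snake_case SRA attribute names).
#' @return Named character vector mapping internal field ids to external
#'   field names; the mapping is a bijection over all seven fields.
#' @export
qc_field_dialect <- function(name = c("sra_snake", "display")) {
  name <- match.arg(name)
  FIELD_DIALECTS[[name]]
}

#' Split a semicolon-separated multi-value string
#'
#' Multiple methods, determinations or issues are exchanged in one cell
#' separated by semicolons. Segments are whitespace-trimmed and empty
#' segments dropped. In lenient mode a string with no semicolon is
#' additionally split on commas, accommodating records written with the
#' comma convention.
#'
#' @param raw Input string (`NA` or empty gives an empty result).
#' @param lenient Also split on commas when no semicolon is present.
#' @return Character vector of values, never containing empty strings.
#' @examples
#' parse_multivalue("Mash; Kraken2; FastANI")
#' parse_multivalue("Quast, Samtools", lenient = TRUE)
#' @export
parse_multivalue <- function(raw, lenient = FALSE) {
  if (length(raw) == 0 || is.na(raw)) return(character())
  sep <- ";"
  if (lenient && !grepl(";", raw, fixed = TRUE)) sep <- ","
  parts <- str_trim(strsplit(raw, sep, fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

# Positional variant for the method-version field: empty segments are kept
# (as NA) so versions stay aligned with their method names.
split_versions <- function(raw, lenient = FALSE) {
  if (length(raw) == 0 || is.na(raw) || !nzchar(str_trim(raw))) return(character())
  sep <- ";"
  if (lenient && !grepl(";", raw, fixed = TRUE)) sep <- ","
  parts <- str_trim(strsplit(raw, sep, fixed = TRUE)[[1]])
  ifelse(nzchar(parts), parts, NA_character_)
}

#' Parse a "label [CURIE]" token
#'
#' Accepts the three encodings in which a picklist value may arrive: the
#' full `"label [PREFIX:digits]"` form, a bare label, or a bare CURIE
#' (identifier-first storage). An opening bracket without a matching
#' trailing `]`, or brackets not enclosing a CURIE, is a malformed token.
#'
#' @param raw Token text.
#' @return List with `label` (may be `NA` for a CURIE-only token) and
#'   `curie` (normalized, may be `NA`).
#' @examples
#' parse_term_string("low percent genome captured [GENEPIO:0100571]")
#' @export
parse_term_string <- function(raw) {
  raw <- str_trim(raw)
  if (!nzchar(raw)) {
    abort_qc("Empty term token.", class = "qctags_malformed_token")
  }
  if (is_curie_shaped(raw)) {
    return(list(label = NA_character_, curie = normalize_curie(raw)))
  }
  m <- str_match(raw, "^(.*?)\\s*\\[([A-Za-z][A-Za-z0-9_]*:[0-9]+)\\]$")
  if (!is.na(m[1, 1])) {
    label <- m[1, 2]
    if (!nzchar(label)) label <- NA_character_
    return(list(label = label, curie = normalize_curie(m[1, 3])))
  }
  if (grepl("[][]", raw)) {
    abort_qc(sprintf("Malformed term token (unbalanced or non-CURIE brackets): '%s'", raw),
             class = "qctags_malformed_token", value = raw)
  }
  list(label = raw, curie = NA_character_)
}

# Canonical separator for emitted multi-value cells.
MULTIVALUE_SEP <- "; "
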