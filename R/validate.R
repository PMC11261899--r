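# Rule engine for the QC-tag best practices.

#' Classify a method version string
#'
#' The standard recommends ISO 8601 dates (`YYYY-MM-DD`) or semantic
#' versions (`X.Y.Z`); anything else is legal (version is a free string)
#' but flagged as best-practice-deviating by rule R3.
#'
#' @param raw Version text.
#' @return `"semver"`, `"iso_date"` or `"other"`.
#' @export
classify_version <- function(raw) {
  if (is.null(raw) || is.na(raw)) return("other")
  raw <- str_trim(raw)
  if (str_detect(raw, "^[0-9]+\\.[0-9]+\\.[0-9]+$")) return("semver")
  if (str_detect(raw, "^[0-9]{4}-[0-9]{2}-[0-9]{2}$")) {
    d <- tryCatch(as.Date(raw, format = "%Y-%m-%d"), error = function(e) NA)
    if (!is.na(d) && format(d, "%Y-%m-%d") == raw) return("iso_date")
  }
  "other"
}

#' The validation rule table
#'
#' @return Tibble describing each rule id, its default severity per profile,
#'   and what it checks.
#' @export
qc_rules <- function() {
  tibble::tribble(
    ~rule_id, ~severity_strict, ~severity_lenient, ~check,
    "R1", "error",   "error",   "QC tags present without a method name",
    "R2", "warning", "warning", "method listed without a version",
    "R3", "warning", "warning", "version neither semantic (X.Y.Z) nor ISO 8601 date",
    "R4", "error",   "error",   "version count differs from method count",
    "R5", "error",   "warning", "value not in the registry picklist (core or extension)",
    "R6", "info",    "info",    "duplicate values within a multi-value list",
    "R7", "error",   "error",   "synthetic lab construct carrying inherited biological-sample fields",
    "R8", "warning", "warning", "term used outside its category / inconsistent determination-issue pairing",
    "R9", "warning", "warning", "Not Applicable mixed with other values",
    "N1", "info",    "info",    "issues reported without an overall determination (note, not a rule)"
  )
}

# BioSample-style attribute names treated as inherited biological-sample
# metadata for rule R7 (synthetic constructs must not inherit sample
# metadata from original biological sources).
INHERITED_SAMPLE_FIELDS <- c(
  "host", "host_disease", "isolation_source", "collection_date",
  "geo_loc_name", "isolate", "strain", "lat_lon"
)

#' Validate a QC record against the best-practice rules
#'
#' Applies the rule table of [qc_rules()]: R1 (tags require a method name),
#' R2/R3 (version presence and format), R4 (version/name count alignment),
#' R5 (picklist membership; error under the strict profile, warning under
#' lenient), R6 (duplicate values), R7 (synthetic-construct metadata
#' isolation), R8 (category placement and determination/issue consistency),
#' R9 (`Not Applicable` exclusivity), plus the info-level note N1 (issues
#' without a determination). All findings are report entries; validation
#' never throws.
#'
#' @param record A `qc_record`.
#' @param registry A [qc_term_registry()] (used for picklist context in
#'   messages; membership itself was established at build/parse time).
#' @param profile `"strict"` or `"lenient"`; affects only R5 severity.
#' @param inherited_fields Passthrough field names treated as inherited
#'   biological-sample metadata for R7.
#' @param severity_overrides Named character vector overriding rule
#'   severities per deployment, e.g. `c(R3 = "info")`.
#' @return A `qc_validation` report: tibble with columns `rule_id`,
#'   `severity`, `field`, `message`, and attribute `passed` (no errors);
#'   see [report_passed()].
#' @export
validate_record <- function(record, registry = qc_term_registry(),
                            profile = c("lenient", "strict"),
                            inherited_fields = INHERITED_SAMPLE_FIELDS,
                            severity_overrides = NULL) {
  profile <- match.arg(profile)
  rules <- qc_rules()
  sev_col <- if (profile == "strict") rules$severity_strict else rules$severity_lenient
  sev <- stats::setNames(sev_col, rules$rule_id)
  if (!is.null(severity_overrides)) sev[names(severity_overrides)] <- severity_overrides

  findings <- list()
  add <- function(rule, field, message) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(rule_id = rule, severity = unname(sev[[rule]]),
                     field = field, message = message)
  }

  m <- record$methods
  named <- m$name[!is.na(m$name)]
  has_tags <- nrow(record$determinations) > 0 || nrow(record$issues) > 0 ||
    !is.null(record$details)
  if (length(named) == 0 && has_tags) {
    add("R1", "method_name",
        "QC determination/issues/details are present but no method name is provided; a method name should always be included.")
  }

  # R4 before R2/R3: a misaligned version list is a counting error, the
  # per-method checks still run on the positional pairing.
  n_named <- length(named)
  if (record$n_versions > 0 && n_named > 0 && record$n_versions != n_named) {
    add("R4", "method_version",
        sprintf("%d version value(s) for %d method name(s); record versions in the same order and number as the method names.",
                record$n_versions, n_named))
  }
  for (i in seq_len(nrow(m))) {
    if (is.na(m$name[i])) next
    if (is.na(m$version[i])) {
      add("R2", "method_version",
          sprintf("Method '%s' has no version; the version of the QC method should be included.", m$name[i]))
    } else if (classify_version(m$version[i]) == "other") {
      add("R3", "method_version",
          sprintf("Version '%s' of method '%s' is neither semantic versioning (X.Y.Z) nor an ISO 8601 date (YYYY-MM-DD).",
                  m$version[i], m$name[i]))
    }
  }

  check_terms <- function(terms, field, category) {
    if (nrow(terms) == 0) return()
    unres <- which(!terms$resolved)
    for (i in unres) {
      add("R5", field,
          sprintf("Value '%s' is not in the %s picklist (core or registered extension); submit a New Term Request or register an extension term.",
                  terms$raw[i], field))
    }
    keys <- term_keys(terms)
    if (anyDuplicated(keys)) {
      add("R6", field, sprintf("Duplicate value(s) in %s: %s.", field,
          paste(unique(terms$label[duplicated(keys)]), collapse = ", ")))
    }
    na_key <- keys == "GENEPIO:0001619"
    if (any(na_key) && !all(na_key)) {
      add("R9", field,
          sprintf("'Not Applicable' is mixed with other values in %s; it should be the sole value.", field))
    }
    misplaced <- which(terms$resolved & !is.na(terms$category) &
                         terms$category != category & !na_key)
    for (i in misplaced) {
      add("R8", field,
          sprintf("Term '%s' is a %s-category term but appears in %s.",
                  terms$label[i], terms$category[i], field))
    }
  }
  check_terms(record$determinations, "determination", "determination")
  check_terms(record$issues, "issues", "issue")

  # Determination/issue consistency: "quality control not performed"
  # alongside reported issues is contradictory enough to warn about.
  det_keys <- term_keys(record$determinations)
  if ("GENEPIO:0100567" %in% det_keys && nrow(record$issues) > 0 &&
      !all(term_keys(record$issues) == "GENEPIO:0001619")) {
    add("R8", "determination",
        "Determination 'quality control not performed' is inconsistent with reported QC issues.")
  }

  if (nrow(record$specimen_role) > 0) {
    role <- record$specimen_role
    if (!role$resolved[1]) {
      add("R5", "specimen_role",
          sprintf("Value '%s' is not in the specimen-role picklist.", role$raw[1]))
    }
    if (any(term_keys(role) == "GENEPIO:0101039")) {
      inherited <- intersect(tolower(names(record$extras)), tolower(inherited_fields))
      if (length(inherited) > 0) {
        add("R7", "specimen_role",
            sprintf("Synthetic lab construct must not inherit biological-sample metadata; remove inherited field(s): %s.",
                    paste(inherited, collapse = ", ")))
      }
    }
  }

  if (nrow(record$issues) > 0 && nrow(record$determinations) == 0 &&
      !all(term_keys(record$issues) == "GENEPIO:0001619")) {
    add("N1", "determination",
        "Issues are reported without an overall determination; consider adding one.")
  }

  report <- if (length(findings) == 0) {
    tibble::tibble(rule_id = character(), severity = character(),
                   field = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
  structure(report, class = c("qc_validation", class(report)),
            passed = !any(report$severity == "error"))
}

#' Did a validation report pass?
#'
#' A report passes iff it contains no error-severity findings; warnings and
#' info notes do not fail a record.
#'
#' @param report A `qc_validation` report.
#' @return Logical scalar.
#' @export
report_passed <- function(report) {
  isTRUE(attr(report, "passed"))
}

#' @export
print.qc_validation <- function(x, ...) {
  status <- if (report_passed(x)) "passed" else "FAILED"
  cat(sprintf("<qc_validation: %s, %d finding(s)>\n", status, nrow(x)))
  if (nrow(x) > 0) NextMethod()
  invisible(x)
}

#' @export
glance.qc_validation <- function(x, ...) {
  tibble::tibble(
    passed = report_passed(x),
    n_errors = sum(x$severity == "error"),
    n_warnings = sum(x$severity == "warning"),
    n_info = sum(x$severity == "info")
  )
}

#' Validate every record in a collection
#'
#' @param collection A [qc_collection()].
#' @inheritParams validate_record
#' @param ... Passed on to [validate_record()].
#' @return A `qc_validation_set`: list with `reports` (per-record
#'   `qc_validation` objects), `passed` (logical vector), and `summary`
#'   (tibble of finding counts by rule and severity).
#' @export
validate_collection <- function(collection, registry = qc_term_registry(),
                                profile = c("lenient", "strict"), ...) {
  profile <- match.arg(profile)
  reports <- lapply(collection$records, validate_record, registry = registry,
                    profile = profile, ...)
  all_findings <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    r <- tibble::as_tibble(reports[[i]])
    if (nrow(r) > 0) r$record <- i
    r
  }))
  summary <- if (nrow(all_findings) == 0) {
    tibble::tibble(rule_id = character(), severity = character(), n = integer())
  } else {
    dplyr::count(all_findings, .data$rule_id, .data$severity, name = "n")
  }
  structure(list(reports = reports,
                 passed = vapply(reports, report_passed, logical(1)),
                 summary = summary),
            class = "qc_validation_set")
}

#' @export
print.qc_validation_set <- function(x, ...) {
  cat(sprintf("<qc_validation_set: %d/%d record(s) passed>\n",
              sum(x$passed), length(x$passed)))
  if (nrow(x$summary) > 0) print(x$summary)
  invisible(x)
}

#' @export
tidy.qc_validation_set <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$reports), function(i) {
    r <- tibble::as_tibble(x$reports[[i]])
    if (nrow(r) == 0) return(NULL)
    dplyr::mutate(r, record = i, .before = 1)
  }))
}

#' @export
glance.qc_validation_set <- function(x, ...) {
  tibble::tibble(
    n_records = length(x$passed),
    n_passed = sum(x$passed),
    n_findings = sum(vapply(x$reports, nrow, integer(1)))
  )
}
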