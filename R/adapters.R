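# Adapters: explicit rule tables translating normalized QC-tool reports
# into standardized tag records. Determination severities (flagged vs
# failed vs minor) follow the conventions each tool community uses; all
# numeric thresholds are configurable arguments with documented defaults —
# QC thresholds differ across laboratories, so only the ncov-tools
# excess-ambiguity cutoff (">5 ambiguous sites") is fixed by the tool
# itself.
#
# Details cells often carry wet-lab context the tool cannot know (Ct
# values, DNA concentrations); every adapter therefore accepts an
# operator-supplied `details` override and otherwise emits a mechanical
# description (or the Not Applicable term when there is nothing to say).

check_tool <- function(report, expected) {
  if (!inherits(report, "qc_tool_report") ||
      tolower(report$tool) != tolower(expected)) {
    abort_qc(sprintf("Adapter mismatch: expected a '%s' report, got '%s'.",
                     expected, if (inherits(report, "qc_tool_report")) report$tool else class(report)[1]),
             class = "qctags_adapter_mismatch")
  }
}

NA_TERM <- "Not Applicable [GENEPIO:0001619]"

adapter_record <- function(registry, tool, version, determinations = NULL,
                           issues = NULL, details = NULL) {
  build_record(registry,
               methods = tool,
               versions = if (is.na(version)) NULL else version,
               determinations = determinations, issues = issues,
               details = details, mode = "strict")
}

#' Adapt an ncov-tools QC summary
#'
#' ncov-tools emits flags rather than a pass/fail call. An
#' ambiguous-consensus-site count strictly greater than `max_ambiguous`
#' (the tool's own ">5 ambiguous sites" excess-ambiguity rule) maps to the
#' determination *sequence flagged for potential quality control issues*
#' with issue *sequence contaminated* (ambiguity may indicate contamination
#' or a real mixed infection); a frameshift flag maps to the same
#' determination with issue *excess frameshift mutations detected*. With no
#' flags raised, a methods-only record is returned — method metadata is
#' valuable even when no issues are reported.
#'
#' @param report A `qc_tool_report` for ncov-tools.
#' @param registry A [qc_term_registry()].
#' @param max_ambiguous Ambiguity threshold (strict `>`; default 5, the
#'   tool's excess-ambiguity rule).
#' @param details Operator-supplied free-text details; when absent and an
#'   issue is emitted with nothing mechanical to report, the details field
#'   carries the *Not Applicable* term.
#' @return A `qc_record`.
#' @export
adapt_ncov_tools <- function(report, registry, max_ambiguous = 5, details = NULL) {
  check_tool(report, "ncov-tools")
  issues <- character()
  mech <- character()
  amb <- report$metrics$ambiguous_sites
  if (!is.null(amb) && amb > max_ambiguous) {
    issues <- c(issues, "sequence contaminated")
    mech <- c(mech, sprintf(">%d ambiguous sites in consensus", max_ambiguous))
  }
  if (any(grepl("frameshift", report$flags, ignore.case = TRUE))) {
    issues <- c(issues, "excess frameshift mutations detected")
  }
  if (length(issues) == 0) {
    return(adapter_record(registry, "ncov-tools", report$version))
  }
  det <- "sequence flagged for potential quality control issues"
  details <- details %||% (if (length(mech)) paste(mech, collapse = "; ") else NA_TERM)
  adapter_record(registry, "ncov-tools", report$version, det, issues, details)
}

#' Adapt per-locus samtools-depth coverage
#'
#' Checks read depth over loci of characteristic importance (e.g. positions
#' conferring antimicrobial resistance). Any target locus with mean depth
#' strictly below `min_depth` fails the sequence with issue *low coverage
#' of characteristic mutations*.
#'
#' @param report A `qc_tool_report` with `per_locus` populated.
#' @inheritParams adapt_ncov_tools
#' @param target_loci Locus names that must be covered; each must appear in
#'   the report.
#' @param min_depth Minimum acceptable mean depth (strict `<`; default 10).
#' @return A `qc_record`.
#' @export
adapt_samtools_depth <- function(report, registry, target_loci, min_depth = 10,
                                 details = NULL) {
  check_tool(report, "samtools depth")
  if (is.null(report$per_locus)) {
    abort_qc("Report has no per-locus depths.", class = "qctags_invalid_report")
  }
  missing <- setdiff(target_loci, report$per_locus$locus)
  if (length(missing) > 0) {
    abort_qc(sprintf("Target locus not in depth report: %s.",
                     paste(missing, collapse = ", ")),
             class = "qctags_missing_locus", loci = missing)
  }
  depths <- report$per_locus[report$per_locus$locus %in% target_loci, ]
  low <- depths$locus[depths$depth < min_depth]
  if (length(low) == 0) {
    return(adapter_record(registry, "samtools depth", report$version))
  }
  adapter_record(registry, "samtools depth", report$version,
                 "sequence failed quality control",
                 "low coverage of characteristic mutations",
                 details %||% sprintf("read depth below %s at: %s", min_depth,
                                      paste(low, collapse = ", ")))
}

# Rule table: FastQC module failures mapped to issue terms. Unmapped
# failing modules still fail the record; they are named in the mechanical
# details instead of carrying an issue term.
FASTQC_ISSUE_MAP <- c(
  "per base sequence quality" = "low quality sequence",
  "per sequence gc content"   = "sequence contaminated"
)

#' Adapt a FastQC module-status report
#'
#' Rule table over the per-module statuses: a failing *Per base sequence
#' quality* module yields issue *low quality sequence*; a failing *Per
#' sequence GC content* module (bimodal GC suggesting a second organism)
#' yields *sequence contaminated*. Any failing module fails the sequence;
#' warnings only give *minor quality control issues identified*; all
#' modules passing gives *no quality control issues identified*.
#'
#' @param report A `qc_tool_report` with `modules` populated.
#' @inheritParams adapt_ncov_tools
#' @param issue_labels Optional named map from canonical issue labels to
#'   the spelling to emit (registered synonyms only), e.g.
#'   `c("sequence contaminated" = "sequenced contaminated")`.
#' @return A `qc_record`.
#' @export
adapt_fastqc <- function(report, registry, details = NULL, issue_labels = NULL) {
  check_tool(report, "FastQC")
  if (is.null(report$modules)) {
    abort_qc("Report has no module statuses.", class = "qctags_invalid_report")
  }
  st <- report$modules
  failing <- st$module[st$status == "fail"]
  issues <- unname(FASTQC_ISSUE_MAP[tolower(failing)])
  unmapped <- failing[is.na(issues)]
  issues <- issues[!is.na(issues)]
  if (!is.null(issue_labels)) {
    hit <- issues %in% names(issue_labels)
    issues[hit] <- unname(issue_labels[issues[hit]])
  }
  if (length(failing) > 0) {
    det <- "sequence failed quality control"
    mech <- sprintf("failing FastQC module(s): %s", paste(failing, collapse = ", "))
  } else if (any(st$status == "warn")) {
    det <- "minor quality control issues identified"
    mech <- sprintf("FastQC warning(s): %s",
                    paste(st$module[st$status == "warn"], collapse = ", "))
  } else {
    det <- "no quality control issues identified"
    mech <- NULL
  }
  adapter_record(registry, "FastQC", report$version, det,
                 if (length(issues)) issues else NULL,
                 details %||% mech)
}

#' Adapt a Kraken2 taxonomic-abundance report
#'
#' A considerable fraction of reads assigned to taxa other than the
#' targeted one indicates contaminating (often host) reads. The off-target
#' fraction is `1 - fraction(target)` among classified reads (unclassified
#' reads excluded from the denominator by default); strictly above
#' `max_offtarget_fraction` it flags the sequence with issue *low signal to
#' noise ratio*.
#'
#' @param report A `qc_tool_report` with `taxa` populated.
#' @inheritParams adapt_ncov_tools
#' @param target_taxon Name of the targeted taxon (must be present in the
#'   report).
#' @param max_offtarget_fraction Tolerated off-target read fraction
#'   (strict `>`; default 0.2).
#' @param exclude_unclassified Drop the `unclassified` row from the
#'   denominator.
#' @return A `qc_record`.
#' @export
adapt_kraken2 <- function(report, registry, target_taxon,
                          max_offtarget_fraction = 0.2,
                          exclude_unclassified = TRUE, details = NULL) {
  check_tool(report, "Kraken2")
  taxa <- report$taxa
  if (is.null(taxa)) {
    abort_qc("Report has no taxon fractions.", class = "qctags_invalid_report")
  }
  if (exclude_unclassified) {
    taxa <- taxa[tolower(taxa$taxon) != "unclassified", , drop = FALSE]
  }
  hit <- tolower(taxa$taxon) == tolower(target_taxon)
  if (!any(hit)) {
    abort_qc(sprintf("Target taxon '%s' not in report.", target_taxon),
             class = "qctags_missing_taxon", taxon = target_taxon)
  }
  total <- sum(taxa$fraction)
  offtarget <- if (total > 0) 1 - sum(taxa$fraction[hit]) / total else 0
  if (offtarget > max_offtarget_fraction) {
    adapter_record(registry, "Kraken2", report$version,
                   "sequence flagged for potential quality control issues",
                   "low signal to noise ratio",
                   details %||% sprintf("%.0f%% of classified reads assigned to taxa other than %s",
                                        100 * offtarget, target_taxon))
  } else {
    adapter_record(registry, "Kraken2", report$version)
  }
}

#' Adapt Nextclade QC flags
#'
#' Nextclade's coverage and missing-data (high N count) QC rules both
#' reflect an incompletely captured genome: either flag fails the sequence
#' with the single issue *low percent genome captured*.
#'
#' @param report A `qc_tool_report` whose `flags` may contain
#'   `"low_coverage"` and/or `"high_N"`.
#' @inheritParams adapt_ncov_tools
#' @return A `qc_record`.
#' @export
adapt_nextclade <- function(report, registry, details = NULL) {
  check_tool(report, "Nextclade")
  raised <- intersect(c("low_coverage", "high_N"), report$flags)
  if (length(raised) == 0) {
    return(adapter_record(registry, "Nextclade", report$version))
  }
  adapter_record(registry, "Nextclade", report$version,
                 "sequence failed quality control",
                 "low percent genome captured",
                 details %||% sprintf("Nextclade QC flag(s): %s",
                                      paste(raised, collapse = ", ")))
}

#' Adapt a Quast + Samtools assembly assessment
#'
#' Combines an assembly-statistics report (Quast) with a mean-depth report
#' (Samtools coverage): a contig count strictly above `max_contigs` yields
#' issue *low quality sequence*, mean depth strictly below
#' `min_mean_depth` yields *low average genome coverage*; either gives the
#' determination *minor quality control issues identified*. The record
#' lists both tools with positionally aligned versions.
#'
#' @param quast A `qc_tool_report` for Quast with metric `n_contigs`.
#' @param samtools A `qc_tool_report` for Samtools with metric `mean_depth`.
#' @inheritParams adapt_ncov_tools
#' @param max_contigs Maximum expected contig count (default 200).
#' @param min_mean_depth Minimum mean fold-coverage (default 30).
#' @return A `qc_record`.
#' @export
adapt_assembly_pair <- function(quast, samtools, registry, max_contigs = 200,
                                min_mean_depth = 30, details = NULL) {
  check_tool(quast, "Quast")
  check_tool(samtools, "Samtools")
  issues <- character()
  mech <- character()
  n_contigs <- quast$metrics$n_contigs
  if (!is.null(n_contigs) && n_contigs > max_contigs) {
    issues <- c(issues, "low quality sequence")
    mech <- c(mech, sprintf("%s contigs (expected at most %s)", n_contigs, max_contigs))
  }
  depth <- samtools$metrics$mean_depth
  if (!is.null(depth) && depth < min_mean_depth) {
    issues <- c(issues, "low average genome coverage")
    mech <- c(mech, sprintf("%sx mean depth (below %sx)", depth, min_mean_depth))
  }
  methods <- tibble::tibble(name = c("Quast", "Samtools"),
                            version = c(quast$version, samtools$version))
  if (length(issues) == 0) {
    return(build_record(registry, methods = methods, mode = "strict"))
  }
  build_record(registry, methods = methods,
               determinations = "minor quality control issues identified",
               issues = issues,
               details = details %||% paste(mech, collapse = "; "),
               mode = "strict")
}

#' Adapt a set of taxonomic-classification calls
#'
#' Compares species calls from several in-silico classifiers, optionally
#' together with the wet-lab identification. If more than one distinct
#' taxon is called, the sequence is flagged with issue *taxonomic
#' designation inconsistent across methods*; unanimous calls yield a
#' methods-only record. Methods and versions are joined in call order.
#'
#' @param calls Tibble (or list of triples) with columns `tool`, `version`,
#'   `taxon` — one classifier call each.
#' @inheritParams adapt_ncov_tools
#' @param wetlab_id Optional taxon identified by standard microbiological
#'   methods, included in the consistency comparison.
#' @return A `qc_record`.
#' @export
adapt_taxonomic_consensus <- function(calls, registry, wetlab_id = NULL,
                                      details = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- tibble::tibble(
      tool = map_chr(calls, 1), version = map_chr(calls, 2),
      taxon = map_chr(calls, 3))
  }
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) {
    abort_qc("No classifier calls provided.", class = "qctags_empty_input")
  }
  methods <- tibble::tibble(name = calls$tool, version = calls$version)
  taxa <- unique(tolower(c(calls$taxon, wetlab_id)))
  if (length(taxa) <= 1) {
    return(build_record(registry, methods = methods, mode = "strict"))
  }
  build_record(registry, methods = methods,
               determinations = "sequence flagged for potential quality control issues",
               issues = "taxonomic designation inconsistent across methods",
               details = details %||% sprintf(
                 "%d distinct taxonomic designations across %d classification method(s)%s",
                 length(taxa), nrow(calls),
                 if (is.null(wetlab_id)) "" else " and wet-lab identification"),
               mode = "strict")
}

#' Default VADR alert-code mapping
#'
#' Maps VADR alert codes to issue terms: early stop codons
#' (`cdsstopn`) to *low coverage of characteristic mutations*, frameshifts
#' (`fsthicnf`/`fstlocnf`) to *excess frameshift mutations detected*, low
#' feature similarity (`lowsimis`/`lowsim5s`/`lowsim3s`) to *low percent
#' genome captured*. Generic spelled-out codes are accepted as aliases.
#'
#' @return Named character vector alert code → issue label.
#' @export
vadr_default_alert_map <- function() {
  c(cdsstopn = "low coverage of characteristic mutations",
    early_stop = "low coverage of characteristic mutations",
    fsthicnf = "excess frameshift mutations detected",
    fstlocnf = "excess frameshift mutations detected",
    frameshift = "excess frameshift mutations detected",
    lowsimis = "low percent genome captured",
    lowsim5s = "low percent genome captured",
    lowsim3s = "low percent genome captured",
    low_feature_similarity = "low percent genome captured")
}

#' Adapt VADR annotation alerts
#'
#' Each alert code maps through `alert_map` to an issue term; duplicate
#' issue terms are deduplicated preserving first occurrence, and any alert
#' flags the sequence. Unmapped alert codes raise a warning and are
#' retained in the details text so no signal is dropped silently.
#'
#' @param report A `qc_tool_report` whose `flags` are VADR alert codes.
#' @inheritParams adapt_ncov_tools
#' @param alert_map Named map alert code → issue label (default
#'   [vadr_default_alert_map()]).
#' @return A `qc_record`.
#' @export
adapt_vadr <- function(report, registry, alert_map = vadr_default_alert_map(),
                       details = NULL) {
  check_tool(report, "VADR")
  alerts <- report$flags
  if (length(alerts) == 0) {
    return(adapter_record(registry, "VADR", report$version))
  }
  mapped <- alert_map[alerts]
  unmapped <- alerts[is.na(mapped)]
  if (length(unmapped) > 0) {
    rlang::warn(sprintf("Unmapped VADR alert code(s): %s (retained in details).",
                        paste(unique(unmapped), collapse = ", ")),
                class = "qctags_unmapped_alert")
  }
  issues <- unique(unname(mapped[!is.na(mapped)]))
  mech <- sprintf("VADR alert(s): %s", paste(alerts, collapse = ", "))
  adapter_record(registry, "VADR", report$version,
                 "sequence flagged for potential quality control issues",
                 if (length(issues)) issues else NULL,
                 details %||% mech)
}

#' Adapt a PHoeNIx pipeline summary
#'
#' An overall `SUCCESS` status with every individual metric `SUCCESS` maps
#' to *sequence passed quality control* with issues and details both *Not
#' Applicable*; any non-`SUCCESS` metric fails the sequence, naming the
#' failing metrics in the details.
#'
#' @param report A `qc_tool_report` with `overall` status and per-metric
#'   statuses in `metrics`.
#' @inheritParams adapt_ncov_tools
#' @return A `qc_record`.
#' @export
adapt_phoenix <- function(report, registry, details = NULL) {
  check_tool(report, "PHoeNIx")
  if (is.null(report$overall)) {
    abort_qc("PHoeNIx report has no overall status.", class = "qctags_parse_error")
  }
  statuses <- unlist(report$metrics)
  failing <- names(statuses)[toupper(statuses) != "SUCCESS"]
  if (toupper(report$overall) == "SUCCESS" && length(failing) == 0) {
    if (length(statuses) == 0) {
      rlang::inform("PHoeNIx report carries an overall SUCCESS but no individual metrics.",
                    class = "qctags_note")
    }
    return(adapter_record(registry, "PHoeNIx", report$version,
                          "sequence passed quality control",
                          "Not Applicable", details %||% NA_TERM))
  }
  adapter_record(registry, "PHoeNIx", report$version,
                 "sequence failed quality control", NULL,
                 details %||% sprintf("failing metric(s): %s",
                                      paste(if (length(failing)) failing else report$overall,
                                            collapse = ", ")))
}
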