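# Normalized QC-tool reports and parsers for their minimal canonical text
# forms. Adapters consume `qc_tool_report` objects; the parsers here read
# the simple tabular shapes each tool's report reduces to. Full
# native-format fidelity (MultiQC-grade) is out of scope.

#' Construct a normalized tool report
#'
#' @param tool Tool name (e.g. `"FastQC"`).
#' @param version Tool/pipeline version string.
#' @param metrics Named list of numeric or text metrics.
#' @param flags Character vector of tool-emitted alert/flag codes.
#' @param per_locus Optional tibble `(locus, depth)` of read depths
#'   (depths must be non-negative).
#' @param taxa Optional tibble `(taxon, fraction)` of read fractions in
#'   `[0, 1]`, summing to at most 1 (tolerance 1e-6).
#' @param modules Optional tibble `(module, status)` of per-module statuses
#'   (`pass`/`warn`/`fail`), as FastQC emits.
#' @param overall Optional overall status string (e.g. PHoeNIx `"SUCCESS"`).
#' @return A `qc_tool_report` object.
#' @export
tool_report <- function(tool, version = NA_character_, metrics = list(),
                        flags = character(), per_locus = NULL, taxa = NULL,
                        modules = NULL, overall = NULL) {
  if (!is.null(taxa)) {
    taxa <- tibble::as_tibble(taxa)
    stopifnot(all(c("taxon", "fraction") %in% names(taxa)))
    if (any(taxa$fraction < 0 | taxa$fraction > 1) ||
        sum(taxa$fraction) > 1 + 1e-6) {
      abort_qc("Taxon read fractions must lie in [0, 1] and sum to at most 1.",
               class = "qctags_invalid_report")
    }
  }
  if (!is.null(per_locus)) {
    per_locus <- tibble::as_tibble(per_locus)
    stopifnot(all(c("locus", "depth") %in% names(per_locus)))
    if (any(per_locus$depth < 0)) {
      abort_qc("Per-locus depths must be non-negative.",
               class = "qctags_invalid_report")
    }
  }
  if (!is.null(modules)) {
    modules <- tibble::as_tibble(modules)
    stopifnot(all(c("module", "status") %in% names(modules)))
    modules$status <- tolower(modules$status)
    bad <- setdiff(unique(modules$status), c("pass", "warn", "fail"))
    if (length(bad) > 0) {
      abort_qc(sprintf("Unknown module status: %s (expected pass/warn/fail).",
                       paste(bad, collapse = ", ")),
               class = "qctags_parse_error")
    }
  }
  structure(list(tool = tool, version = as.character(version),
                 metrics = metrics, flags = flags, per_locus = per_locus,
                 taxa = taxa, modules = modules, overall = overall),
            class = "qc_tool_report")
}

#' @export
print.qc_tool_report <- function(x, ...) {
  cat(sprintf("<qc_tool_report: %s %s>\n", x$tool,
              if (is.na(x$version)) "(no version)" else x$version))
  invisible(x)
}

read_report_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readr::read_lines(text, progress = FALSE)
  } else if (length(text) == 1) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text[nzchar(str_trim(text))]
}

#' Parse a FastQC summary
#'
#' Canonical form: the `summary.txt` FastQC ships — one line per module,
#' `STATUS<TAB>Module name<TAB>filename` with status `PASS`/`WARN`/`FAIL`.
#'
#' @param text File path, single string, or character vector of lines.
#' @param version Tool version to attach.
#' @return A `qc_tool_report` with `modules` populated.
#' @export
parse_fastqc_summary <- function(text, version = NA_character_) {
  lines <- read_report_lines(text)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tool_report("FastQC", version = version,
              modules = tibble::tibble(
                module = map_chr(parts, 2),
                status = tolower(map_chr(parts, 1))))
}

#' Parse a Kraken2 report
#'
#' Canonical form: the standard 6-column Kraken2 report (percentage of
#' reads in clade, clade read count, taxon read count, rank code, taxid,
#' indented name). Unclassified (`U`) and species-level (`S`) rows are
#' turned into read fractions; other ranks are ignored.
#'
#' @inheritParams parse_fastqc_summary
#' @return A `qc_tool_report` with `taxa` populated (fractions of total
#'   reads).
#' @export
parse_kraken2_report <- function(text, version = NA_character_) {
  lines <- read_report_lines(text)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rank <- map_chr(parts, 4)
  keep <- rank %in% c("U", "S")
  taxa <- tibble::tibble(
    taxon = str_trim(map_chr(parts[keep], 6)),
    fraction = as.numeric(map_chr(parts[keep], 1)) / 100
  )
  tool_report("Kraken2", version = version, taxa = taxa)
}

#' Parse samtools-depth output aggregated per locus
#'
#' Canonical form: the 3-column `samtools depth` TSV
#' (`sequence/region<TAB>position<TAB>depth`), with the target loci
#' extracted as separate sequences or regions; depth is averaged per
#' sequence name.
#'
#' @inheritParams parse_fastqc_summary
#' @return A `qc_tool_report` with `per_locus` mean depths.
#' @export
parse_samtools_depth <- function(text, version = NA_character_) {
  lines <- read_report_lines(text)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  d <- tibble::tibble(locus = map_chr(parts, 1),
                      depth = as.numeric(map_chr(parts, 3)))
  per_locus <- dplyr::summarise(dplyr::group_by(d, .data$locus),
                                depth = mean(.data$depth), .groups = "drop")
  tool_report("samtools depth", version = version, per_locus = per_locus)
}

#' Parse a Quast report
#'
#' Canonical form: the tab-separated `report.tsv` key/value layout
#' (`metric<TAB>value`). The `# contigs` row is exposed as metric
#' `n_contigs`.
#'
#' @inheritParams parse_fastqc_summary
#' @return A `qc_tool_report` with `metrics` populated.
#' @export
parse_quast_report <- function(text, version = NA_character_) {
  lines <- read_report_lines(text)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  metrics <- stats::setNames(lapply(parts, function(p) {
    v <- p[2]
    if (grepl("^[0-9.]+$", v)) as.numeric(v) else v
  }), map_chr(parts, 1))
  if ("# contigs" %in% names(metrics)) metrics$n_contigs <- metrics[["# contigs"]]
  tool_report("Quast", version = version, metrics = metrics)
}

#' Parse an ncov-tools QC summary
#'
#' Canonical form: tab-separated `key<TAB>value` pairs; recognized keys are
#' `ambiguous_sites` (count of IUPAC-ambiguous consensus sites) and `flags`
#' (semicolon-separated flag codes such as `frameshift`).
#'
#' @inheritParams parse_fastqc_summary
#' @return A `qc_tool_report` with `metrics$ambiguous_sites` and `flags`.
#' @export
parse_ncov_tools_summary <- function(text, version = NA_character_) {
  lines <- read_report_lines(text)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- stats::setNames(map_chr(parts, 2), map_chr(parts, 1))
  metrics <- list()
  if ("ambiguous_sites" %in% names(kv)) {
    metrics$ambiguous_sites <- as.numeric(kv[["ambiguous_sites"]])
  }
  flags <- if ("flags" %in% names(kv)) parse_multivalue(kv[["flags"]]) else character()
  tool_report("ncov-tools", version = version, metrics = metrics, flags = flags)
}

#' Parse a Nextclade QC check table
#'
#' Canonical form: tab-separated `check<TAB>status` rows with statuses
#' `good`/`mediocre`/`bad` (as Nextclade's per-rule QC statuses reduce to);
#' checks `coverage` and `missing_data` map to the `low_coverage` and
#' `high_N` flags when bad.
#'
#' @inheritParams parse_fastqc_summary
#' @return A `qc_tool_report` with `flags` populated.
#' @export
parse_nextclade_qc <- function(text, version = NA_character_) {
  lines <- read_report_lines(text)
  lines <- lines[!startsWith(lines, "check\t")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  check <- map_chr(parts, 1)
  status <- tolower(map_chr(parts, 2))
  flags <- c(
    if (any(check == "coverage" & status == "bad")) "low_coverage",
    if (any(check == "missing_data" & status == "bad")) "high_N"
  )
  tool_report("Nextclade", version = version, flags = flags %||% character())
}

#' Parse a VADR alert list
#'
#' Canonical form: one alert code per line (first whitespace-separated
#' token), as extracted from VADR's `.alt` output.
#'
#' @inheritParams parse_fastqc_summary
#' @return A `qc_tool_report` with `flags` holding the alert codes.
#' @export
parse_vadr_alerts <- function(text, version = NA_character_) {
  lines <- read_report_lines(text)
  codes <- map_chr(strsplit(str_trim(lines), "\\s+"), 1)
  tool_report("VADR", version = version, flags = codes)
}

#' Parse a PHoeNIx summary table
#'
#' Canonical form: tab-separated `metric<TAB>status` rows; the row with
#' metric `overall` (case-insensitive; `Overall_Status` also accepted)
#' carries the pipeline's overall status, all other rows are individual
#' quality metrics.
#'
#' @inheritParams parse_fastqc_summary
#' @return A `qc_tool_report` with `overall` and per-metric statuses in
#'   `metrics`.
#' @export
parse_phoenix_summary <- function(text, version = NA_character_) {
  lines <- read_report_lines(text)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  key <- map_chr(parts, 1)
  val <- map_chr(parts, 2)
  is_overall <- tolower(key) %in% c("overall", "overall_status")
  metrics <- stats::setNames(as.list(val[!is_overall]), key[!is_overall])
  tool_report("PHoeNIx", version = version, metrics = metrics,
              overall = if (any(is_overall)) val[which(is_overall)[1]] else NULL)
}
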