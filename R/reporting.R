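# Determination-breakdown reporting (pilot-style) and seeded synthetic
# fixture generation.

#' Summarize determinations over a collection
#'
#' Counts records per determination category and reports integer-rounded
#' percentages, the reporting style used for network pilot studies ("61 %
#' were classified as having 'no quality control issues'"). By default a
#' record contributes once to each *distinct* determination category it
#' carries (a synthetic-mix record with both a pass and a fail
#' determination counts under both, so counts can exceed the record total);
#' `count = "first"` switches to first-determination-only counting.
#' Percentages are `100 * n / total` rounded half-up to the nearest
#' integer, where `total` is the number of records carrying at least one
#' determination; rounded percentages are not renormalized to sum to 100.
#'
#' @param collection A [qc_collection()].
#' @param count `"per_category"` (default) or `"first"`.
#' @return A `qc_breakdown`: tibble with columns `determination`, `n`,
#'   `percent`, and attribute `total`.
#' @export
summarize_determinations <- function(collection, count = c("per_category", "first")) {
  count <- match.arg(count)
  labels_per_record <- lapply(collection$records, function(rec) {
    d <- rec$determinations
    if (nrow(d) == 0) return(character())
    labs <- ifelse(d$resolved, d$label, d$raw)
    labs <- labs[!duplicated(tolower(labs))]
    if (count == "first") labs[1] else labs
  })
  counted <- labels_per_record[lengths(labels_per_record) > 0]
  total <- length(counted)
  if (total == 0) {
    out <- tibble::tibble(determination = character(), n = integer(),
                          percent = numeric())
    return(structure(out, class = c("qc_breakdown", class(out)), total = 0L))
  }
  all_labels <- unlist(counted)
  tab <- table(factor(all_labels, levels = unique(all_labels)))
  out <- tibble::tibble(
    determination = names(tab),
    n = as.integer(tab),
    percent = floor(100 * as.integer(tab) / total + 0.5)  # half-up
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$n))
  structure(out, class = c("qc_breakdown", class(out)), total = as.integer(total))
}

#' @export
print.qc_breakdown <- function(x, ...) {
  cat(sprintf("<qc_breakdown: %d record(s) with determinations>\n", attr(x, "total")))
  NextMethod()
}

#' @export
glance.qc_breakdown <- function(x, ...) {
  tibble::tibble(total = attr(x, "total"), n_categories = nrow(x),
                 percent_sum = sum(x$percent))
}

# Versions attached to generated method names; unknown tools fall back to
# a generic semantic version.
FIXTURE_TOOL_VERSIONS <- c(
  "GalaxyTrakr SSQuAWK" = "1.0.4",
  "CFSAN Wastewater Analysis Pipeline (C-WAP)" = "2.1.0",
  "ncov-tools" = "1.9.1", "FastQC" = "0.12.0", "Kraken2" = "2.1.3",
  "PHoeNIx" = "2.1.0", "Nextclade" = "3.1.0", "VADR" = "1.6.3"
)

#' Generate a synthetic record collection
#'
#' Draws `n_records` strictly-valid QC records with determination
#' categories sampled from `category_weights` and method names from
#' `tool_mix`. The defaults emulate the GenomeTrakr wastewater pilot: the
#' 0.61/0.10/0.28/0.01 category mix (with the network's CURIE-less
#' extension determination `"significant quality control issues"`) over
#' its two analysis pipelines. Weight labels not present in the registry
#' are registered as extension terms automatically so every generated
#' record passes strict validation. Generation is deterministic for a
#' fixed seed and never touches the global random state.
#'
#' @param n_records Number of records.
#' @param category_weights Named nonnegative weights over determination
#'   labels (at least one positive).
#' @param tool_mix Named nonnegative weights over method names.
#' @param seed Integer seed (threaded explicitly).
#' @param registry A [qc_term_registry()].
#' @return A [qc_collection()]; the (possibly extended) registry used is
#'   attached as attribute `registry`.
#' @export
generate_fixture_collection <- function(n_records,
                                        category_weights = c(
                                          "no quality control issues identified" = 0.61,
                                          "minor quality control issues identified" = 0.10,
                                          "sequence flagged for potential quality control issues" = 0.28,
                                          "significant quality control issues" = 0.01),
                                        tool_mix = c(
                                          "GalaxyTrakr SSQuAWK" = 0.6,
                                          "CFSAN Wastewater Analysis Pipeline (C-WAP)" = 0.4),
                                        seed = 1L,
                                        registry = qc_term_registry()) {
  stopifnot(n_records >= 0, all(category_weights >= 0), any(category_weights > 0),
            all(tool_mix >= 0), any(tool_mix > 0))
  for (lab in names(category_weights)) {
    known <- tryCatch({resolve_label(registry, lab, "determination"); TRUE},
                      qctags_error = function(e) FALSE)
    if (!known) registry <- register_extension(registry, lab, "determination")
  }
  issue_pool <- registry$label[registry$category == "issue" &
                                 registry$provenance == "core"]
  issue_bearing <- c("minor quality control issues identified",
                     "sequence flagged for potential quality control issues",
                     "sequence failed quality control",
                     "significant quality control issues")

  records <- withr::with_seed(seed, {
    dets <- sample(names(category_weights), n_records, replace = TRUE,
                   prob = category_weights)
    tools <- sample(names(tool_mix), n_records, replace = TRUE, prob = tool_mix)
    lapply(seq_len(n_records), function(i) {
      version <- unname(FIXTURE_TOOL_VERSIONS[tools[i]])
      if (is.na(version)) version <- "1.0.0"
      issues <- NULL
      if (tolower(dets[i]) %in% issue_bearing) {
        issues <- sample(issue_pool, sample(1:2, 1))
      }
      build_record(registry, methods = tools[i], versions = version,
                   determinations = dets[i], issues = issues,
                   mode = "strict")
    })
  })
  out <- qc_collection(records, dialect = "sra_snake")
  attr(out, "registry") <- registry
  out
}

#' Generate a synthetic tool report
#'
#' Produces a normalized tool report reproducing one of the worked-example
#' scenarios (`scenario = 1..10`, matching that scenario's committed
#' fixture) or a clean report whose adapter emits no issues
#' (`scenario = "clean"`). Clean reports draw benign metric values
#' deterministically from `seed`.
#'
#' @param tool Tool name among the supported adapters.
#' @param scenario Worked-example id (1-10) or `"clean"`.
#' @param seed Integer seed for clean-report jitter.
#' @return A `qc_tool_report`.
#' @export
generate_tool_report <- function(tool, scenario = "clean", seed = 1L) {
  tools <- c("ncov-tools", "samtools depth", "FastQC", "Kraken2", "Nextclade",
             "Quast", "Samtools", "VADR", "PHoeNIx")
  if (!tolower(tool) %in% tolower(tools)) {
    abort_qc(sprintf("Unsupported tool '%s'.", tool), class = "qctags_unsupported_tool")
  }
  if (!identical(scenario, "clean")) {
    stopifnot(scenario %in% 1:10)
    ex <- worked_example(as.integer(scenario))
    reports <- ex$inputs[vapply(ex$inputs, inherits, logical(1), "qc_tool_report")]
    for (r in reports) if (tolower(r$tool) == tolower(tool)) return(r)
    abort_qc(sprintf("Scenario %s has no '%s' report.", scenario, tool),
             class = "qctags_unsupported_tool")
  }
  withr::with_seed(seed, {
    switch(tolower(tool),
      "ncov-tools" = tool_report("ncov-tools", "1.9.1",
                                 metrics = list(ambiguous_sites = sample(0:5, 1))),
      "samtools depth" = tool_report("samtools depth", "1.19",
                                     per_locus = tibble::tibble(
                                       locus = c("rpoB", "katG", "gyrA"),
                                       depth = stats::runif(3, 30, 120))),
      "fastqc" = tool_report("FastQC", "0.12.0",
                             modules = tibble::tibble(
                               module = c("Per base sequence quality",
                                          "Per sequence GC content",
                                          "Adapter Content"),
                               status = "pass")),
      "kraken2" = {
        target <- stats::runif(1, 0.9, 0.99)
        tool_report("Kraken2", "2.1.3",
                    taxa = tibble::tibble(taxon = c("SARS-CoV-2", "Homo sapiens"),
                                          fraction = c(target, 1 - target)))
      },
      "nextclade" = tool_report("Nextclade", "3.1.0"),
      "quast" = tool_report("Quast", "5.2.0",
                            metrics = list(n_contigs = sample(20:150, 1))),
      "samtools" = tool_report("Samtools", "1.19",
                               metrics = list(mean_depth = stats::runif(1, 40, 200))),
      "vadr" = tool_report("VADR", "1.6.3"),
      "phoenix" = tool_report("PHoeNIx", "2.1.0", overall = "SUCCESS",
                              metrics = stats::setNames(
                                as.list(rep("SUCCESS", 27)),
                                sprintf("metric_%02d", 1:27)))
    )
  })
}
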