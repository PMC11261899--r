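# Scenario fixtures: eleven worked examples spanning the standard's
# adapters (1-10) and the synthetic-lab-construct annotation (11). Each
# fixture carries the scenario inputs (a normalized tool report plus the
# operator-supplied wet-lab details) and the expected rendered field
# values. These are first-class, generated-in-code fixtures — nothing is
# downloaded.

#' Worked-example scenario fixtures
#'
#' Returns the fixture for one of the eleven worked-example scenarios:
#' the scenario inputs (`$inputs`), the adapter that consumes them
#' (`$adapter`, `NA` for the direct-annotation scenario 11), and the
#' expected rendered field map in the snake_case dialect (`$expected`).
#' Scenario 7 joins its method names/versions with the canonical `"; "`
#' separator; scenario 4 expects the as-written synonym spelling
#' `"sequenced contaminated"`, which [run_worked_example()] reproduces via
#' the adapter's `issue_labels` override and as-given rendering.
#'
#' @param id Scenario id, 1-11.
#' @return List with `id`, `adapter`, `inputs`, `labels`, `expected`.
#' @seealso [run_worked_example()]
#' @export
worked_example <- function(id) {
  stopifnot(length(id) == 1, id %in% 1:11)
  f <- function(...) stats::setNames(c(...)[c(TRUE, FALSE)], c(...)[c(FALSE, TRUE)])
  ex <- switch(as.character(id),
    "1" = list(
      adapter = "adapt_ncov_tools",
      inputs = list(
        report = tool_report("ncov-tools", "1.9.1",
                             metrics = list(ambiguous_sites = 7)),
        details = ">5 ambiguous sites in consensus, sequence indicative of contamination or real mixed infection"),
      expected = c(
        quality_control_method_name = "ncov-tools",
        quality_control_method_version = "1.9.1",
        quality_control_determination = "sequence flagged for potential quality control issues [GENEPIO:0100566]",
        quality_control_issues = "sequence contaminated [GENEPIO:0100569]",
        quality_control_details = ">5 ambiguous sites in consensus, sequence indicative of contamination or real mixed infection")),
    "2" = list(
      adapter = "adapt_ncov_tools",
      inputs = list(
        report = tool_report("ncov-tools", "1.9.1", flags = "frameshift")),
      expected = c(
        quality_control_method_name = "ncov-tools",
        quality_control_method_version = "1.9.1",
        quality_control_determination = "sequence flagged for potential quality control issues [GENEPIO:0100566]",
        quality_control_issues = "excess frameshift mutations detected [GENEPIO:0100751]",
        quality_control_details = "Not Applicable [GENEPIO:0001619]")),
    "3" = list(
      adapter = "adapt_samtools_depth",
      inputs = list(
        report = tool_report("samtools depth", "1.19",
                             per_locus = tibble::tibble(locus = c("rpoB", "katG"),
                                                        depth = c(3, 40))),
        target_loci = c("rpoB", "katG"),
        min_depth = 10,
        details = "low DNA concentration"),
      expected = c(
        quality_control_method_name = "samtools depth",
        quality_control_method_version = "1.19",
        quality_control_determination = "sequence failed quality control [GENEPIO:0100564]",
        quality_control_issues = "low coverage of characteristic mutations [GENEPIO:0100575]",
        quality_control_details = "low DNA concentration")),
    "4" = list(
      adapter = "adapt_fastqc",
      labels = "as_given",
      inputs = list(
        report = tool_report("FastQC", "0.12.0",
                             modules = tibble::tibble(
                               module = c("Per base sequence quality",
                                          "Per sequence GC content"),
                               status = c("fail", "fail"))),
        details = "contaminated cultured isolate",
        issue_labels = c("sequence contaminated" = "sequenced contaminated")),
      expected = c(
        quality_control_method_name = "FastQC",
        quality_control_method_version = "0.12.0",
        quality_control_determination = "sequence failed quality control [GENEPIO:0100564]",
        quality_control_issues = "low quality sequence [GENEPIO:0100568]; sequenced contaminated [GENEPIO:0100569]",
        quality_control_details = "contaminated cultured isolate")),
    "5" = list(
      adapter = "adapt_kraken2",
      inputs = list(
        report = tool_report("Kraken2", "2.1.3",
                             taxa = tibble::tibble(
                               taxon = c("SARS-CoV-2", "Homo sapiens"),
                               fraction = c(0.55, 0.45))),
        target_taxon = "SARS-CoV-2",
        details = "high host reads present from clinical specimen"),
      expected = c(
        quality_control_method_name = "Kraken2",
        quality_control_method_version = "2.1.3",
        quality_control_determination = "sequence flagged for potential quality control issues [GENEPIO:0100566]",
        quality_control_issues = "low signal to noise ratio [GENEPIO:0100574]",
        quality_control_details = "high host reads present from clinical specimen")),
    "6" = list(
      adapter = "adapt_nextclade",
      inputs = list(
        report = tool_report("Nextclade", "3.1.0",
                             flags = c("low_coverage", "high_N")),
        details = "Ct value of 35"),
      expected = c(
        quality_control_method_name = "Nextclade",
        quality_control_method_version = "3.1.0",
        quality_control_determination = "sequence failed quality control [GENEPIO:0100564]",
        quality_control_issues = "low percent genome captured [GENEPIO:0100571]",
        quality_control_details = "Ct value of 35")),
    "7" = list(
      adapter = "adapt_assembly_pair",
      inputs = list(
        quast = tool_report("Quast", "5.2.0", metrics = list(n_contigs = 400)),
        samtools = tool_report("Samtools", "1.19", metrics = list(mean_depth = 15)),
        details = "high number of samples multiplexed on same sequencing run"),
      expected = c(
        quality_control_method_name = "Quast; Samtools",
        quality_control_method_version = "5.2.0; 1.19",
        quality_control_determination = "minor quality control issues identified [GENEPIO:0100565]",
        quality_control_issues = "low quality sequence [GENEPIO:0100568]; low average genome coverage [GENEPIO:0100570]",
        quality_control_details = "high number of samples multiplexed on same sequencing run")),
    "8" = list(
      adapter = "adapt_taxonomic_consensus",
      inputs = list(
        calls = tibble::tibble(
          tool = c("Mash", "Kraken2", "FastANI"),
          version = c("2.3", "2.1.3", "1.34"),
          taxon = c("Salmonella enterica subsp. enterica",
                    "Salmonella enterica subsp. salamae",
                    "Salmonella enterica subsp. enterica")),
        wetlab_id = "Salmonella enterica subsp. diarizonae",
        details = "WGS species identification inconsistent across multiple taxonomic classification methods and inconsistent with identification from culture. Potential novel species/subspecies and/or underrepresented in public repository databases."),
      expected = c(
        quality_control_method_name = "Mash; Kraken2; FastANI",
        quality_control_method_version = "2.3; 2.1.3; 1.34",
        quality_control_determination = "sequence flagged for potential quality control issues [GENEPIO:0100566]",
        quality_control_issues = "taxonomic designation inconsistent across methods [GENEPIO:0101038]",
        quality_control_details = "WGS species identification inconsistent across multiple taxonomic classification methods and inconsistent with identification from culture. Potential novel species/subspecies and/or underrepresented in public repository databases.")),
    "9" = list(
      adapter = "adapt_vadr",
      inputs = list(
        report = tool_report("VADR", "1.6.3",
                             flags = c("lowsimis", "cdsstopn", "fsthicnf")),
        details = "multi-freeze thaw cycles for specimen. Amplicon drop-out."),
      expected = c(
        quality_control_method_name = "VADR",
        quality_control_method_version = "1.6.3",
        quality_control_determination = "sequence flagged for potential quality control issues [GENEPIO:0100566]",
        quality_control_issues = "low percent genome captured [GENEPIO:0100571]; low coverage of characteristic mutations [GENEPIO:0100575]; excess frameshift mutations detected [GENEPIO:0100751]",
        quality_control_details = "multi-freeze thaw cycles for specimen. Amplicon drop-out.")),
    "10" = list(
      adapter = "adapt_phoenix",
      inputs = list(
        report = tool_report("PHoeNIx", "2.1.0", overall = "SUCCESS",
                             metrics = stats::setNames(
                               as.list(rep("SUCCESS", 27)),
                               sprintf("metric_%02d", 1:27)))),
      expected = c(
        quality_control_method_name = "PHoeNIx",
        quality_control_method_version = "2.1.0",
        quality_control_determination = "sequence passed quality control [GENEPIO:0100563]",
        quality_control_issues = "Not Applicable [GENEPIO:0001619]",
        quality_control_details = "Not Applicable [GENEPIO:0001619]")),
    "11" = list(
      adapter = NA_character_,
      inputs = list(
        fields = c(
          quality_control_method_name = "ncov-tools",
          quality_control_method_version = "1.9.1",
          quality_control_determination = "sequence passed quality control [GENEPIO:0100563]; sequence failed quality control [GENEPIO:0100564]",
          quality_control_issues = "sequence flagged for potential quality control issues [GENEPIO:0100566]; low coverage of characteristic mutations [GENEPIO:0100575]; sequence contaminated [GENEPIO:0100569]; low signal to noise ratio [GENEPIO:0100574]",
          quality_control_details = "Various quality control issues may arise depending on the mixture ratio for each sample and the particular mutations of each variant. Where one sample was added at a low level the sequence may pass quality control.",
          experimental_specimen_role_type = "synthetic lab construct [GENEPIO:0101039]",
          experimental_specimen_details = "two different SARS-CoV-2 variants were mixed at varying ratios and whole genome sequenced to determine if our QC analysis would flag them with quality issues and at what level a mixture or potential contamination would be detected.")),
      expected = c(
        quality_control_method_name = "ncov-tools",
        quality_control_method_version = "1.9.1",
        quality_control_determination = "sequence passed quality control [GENEPIO:0100563]; sequence failed quality control [GENEPIO:0100564]",
        quality_control_issues = "sequence flagged for potential quality control issues [GENEPIO:0100566]; low coverage of characteristic mutations [GENEPIO:0100575]; sequence contaminated [GENEPIO:0100569]; low signal to noise ratio [GENEPIO:0100574]",
        quality_control_details = "Various quality control issues may arise depending on the mixture ratio for each sample and the particular mutations of each variant. Where one sample was added at a low level the sequence may pass quality control.",
        experimental_specimen_role_type = "synthetic lab construct [GENEPIO:0101039]",
        experimental_specimen_details = "two different SARS-CoV-2 variants were mixed at varying ratios and whole genome sequenced to determine if our QC analysis would flag them with quality issues and at what level a mixture or potential contamination would be detected."))
  )
  ex$id <- id
  ex$labels <- ex$labels %||% "canonical"
  ex
}

#' Run a worked-example scenario through the pipeline
#'
#' Executes the scenario's adapter on its fixture inputs (scenario 11, the
#' synthetic-construct annotation, is parsed directly from its field map in
#' lenient mode — its issues field cross-places a determination-category
#' term, which the validator reports as R8).
#'
#' @param id Scenario id, 1-11.
#' @param registry A [qc_term_registry()].
#' @return A `qc_record`.
#' @export
run_worked_example <- function(id, registry = qc_term_registry()) {
  ex <- worked_example(id)
  if (is.na(ex$adapter)) {
    return(parse_record(ex$inputs$fields, registry = registry,
                        dialect = "sra_snake", mode = "lenient"))
  }
  do.call(ex$adapter, c(ex$inputs, list(registry = registry)))
}

#' All eleven worked examples as a collection
#'
#' @param registry A [qc_term_registry()].
#' @return A [qc_collection()] of the eleven scenario records.
#' @export
worked_example_collection <- function(registry = qc_term_registry()) {
  qc_collection(lapply(1:11, run_worked_example, registry = registry),
                dialect = "sra_snake")
}
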