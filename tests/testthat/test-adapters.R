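issue_curies <- function(rec) rec$issues$curie
det_label <- function(rec) rec$determinations$label

test_that("ncov-tools adapter applies the strict >5 ambiguity rule and frameshift flag", {
  reg <- test_registry()
  # boundary oracle: sweep counts 0..10 against the published ">5" rule
  for (k in 0:10) {
    rec <- adapt_ncov_tools(
      tool_report("ncov-tools", "1.9.1", metrics = list(ambiguous_sites = k)), reg)
    expect_equal(nrow(rec$issues) > 0, k > 5, info = sprintf("count %d", k))
  }
  five <- adapt_ncov_tools(
    tool_report("ncov-tools", "1.9.1", metrics = list(ambiguous_sites = 5)), reg)
  expect_equal(nrow(five$determinations), 0L)  # methods-only record
  expect_equal(five$methods$name, "ncov-tools")

  fs <- adapt_ncov_tools(tool_report("ncov-tools", "1.9.1", flags = "frameshift"), reg)
  expect_equal(issue_curies(fs), "GENEPIO:0100751")
  expect_equal(fs$details, "Not Applicable [GENEPIO:0001619]")

  expect_error(adapt_ncov_tools(tool_report("FastQC"), reg),
               class = "qctags_adapter_mismatch")
})

test_that("samtools-depth adapter fails loci strictly below the depth floor", {
  reg <- test_registry()
  report <- tool_report("samtools depth", "1.19",
                        per_locus = tibble::tibble(locus = c("rpoB", "katG"),
                                                   depth = c(3, 40)))
  rec <- adapt_samtools_depth(report, reg, target_loci = c("rpoB", "katG"),
                              min_depth = 10)
  expect_equal(det_label(rec), "sequence failed quality control")
  expect_equal(issue_curies(rec), "GENEPIO:0100575")

  at_floor <- tool_report("samtools depth", "1.19",
                          per_locus = tibble::tibble(locus = "rpoB", depth = 10))
  expect_equal(nrow(adapt_samtools_depth(at_floor, reg, "rpoB", 10)$issues), 0L)

  expect_error(adapt_samtools_depth(report, reg, target_loci = "gyrA"),
               class = "qctags_missing_locus")
})

test_that("FastQC adapter follows its module-status rule table", {
  reg <- test_registry()
  mk <- function(pbq, gc, extra = NULL) {
    mods <- tibble::tibble(
      module = c("Per base sequence quality", "Per sequence GC content"),
      status = c(pbq, gc))
    if (!is.null(extra)) mods <- rbind(mods, extra)
    tool_report("FastQC", "0.12.0", modules = mods)
  }
  # rule-table oracle over status combinations
  for (pbq in c("pass", "warn", "fail")) {
    for (gc in c("pass", "warn", "fail")) {
      rec <- adapt_fastqc(mk(pbq, gc), reg)
      expected_det <- if (any(c(pbq, gc) == "fail")) "sequence failed quality control"
        else if (any(c(pbq, gc) == "warn")) "minor quality control issues identified"
        else "no quality control issues identified"
      expect_equal(det_label(rec), expected_det, info = paste(pbq, gc))
      expect_equal("GENEPIO:0100568" %in% issue_curies(rec), pbq == "fail")
      expect_equal("GENEPIO:0100569" %in% issue_curies(rec), gc == "fail")
    }
  }
  all_pass <- adapt_fastqc(mk("pass", "pass"), reg)
  expect_equal(all_pass$determinations$curie, "GENEPIO:0100562")
  # unmapped failing module still fails the record, named in details
  odd <- adapt_fastqc(mk("pass", "pass",
    tibble::tibble(module = "Adapter Content", status = "fail")), reg)
  expect_equal(det_label(odd), "sequence failed quality control")
  expect_equal(nrow(odd$issues), 0L)
  expect_match(odd$details, "Adapter Content")
  expect_error(tool_report("FastQC", modules = tibble::tibble(
    module = "x", status = "maybe")), class = "qctags_parse_error")
})

test_that("Kraken2 adapter flags off-target fractions strictly above threshold", {
  reg <- test_registry()
  mk <- function(target_frac, unclassified = 0) {
    taxa <- tibble::tibble(
      taxon = c("SARS-CoV-2", "Homo sapiens", "unclassified"),
      fraction = c(target_frac, 1 - target_frac - unclassified, unclassified))
    tool_report("Kraken2", "2.1.3", taxa = taxa[taxa$fraction > 0, ])
  }
  flagged <- adapt_kraken2(mk(0.55), reg, "SARS-CoV-2", 0.2)
  expect_equal(issue_curies(flagged), "GENEPIO:0100574")
  expect_equal(det_label(flagged),
               "sequence flagged for potential quality control issues")

  pure <- adapt_kraken2(mk(1.0), reg, "SARS-CoV-2", 0.2)
  expect_equal(nrow(pure$issues), 0L)
  # boundary: off-target exactly at the threshold does not flag
  at <- adapt_kraken2(mk(0.8), reg, "SARS-CoV-2", max_offtarget_fraction = 0.2)
  expect_equal(nrow(at$issues), 0L)
  # unclassified excluded from the denominator by default
  excl <- adapt_kraken2(mk(0.5, unclassified = 0.4), reg, "SARS-CoV-2", 0.2)
  expect_equal(nrow(excl$issues), 0L)  # 1/6 off-target among classified
  expect_error(adapt_kraken2(mk(0.9), reg, "MPOX"), class = "qctags_missing_taxon")
})

test_that("Nextclade adapter folds coverage/N flags into one captured-genome issue", {
  reg <- test_registry()
  both <- adapt_nextclade(tool_report("Nextclade", "3.1.0",
                                      flags = c("low_coverage", "high_N")), reg)
  expect_equal(issue_curies(both), "GENEPIO:0100571")
  one <- adapt_nextclade(tool_report("Nextclade", "3.1.0", flags = "low_coverage"), reg)
  expect_equal(issue_curies(one), "GENEPIO:0100571")
  clean <- adapt_nextclade(tool_report("Nextclade", "3.1.0"), reg)
  expect_equal(nrow(clean$issues), 0L)
})

test_that("assembly-pair adapter combines Quast and Samtools with aligned versions", {
  reg <- test_registry()
  mk <- function(contigs, depth) {
    list(quast = tool_report("Quast", "5.2.0", metrics = list(n_contigs = contigs)),
         samtools = tool_report("Samtools", "1.19", metrics = list(mean_depth = depth)))
  }
  r <- mk(400, 15)
  rec <- adapt_assembly_pair(r$quast, r$samtools, reg)
  expect_equal(rec$methods$name, c("Quast", "Samtools"))
  expect_equal(rec$methods$version, c("5.2.0", "1.19"))
  expect_equal(issue_curies(rec), c("GENEPIO:0100568", "GENEPIO:0100570"))
  expect_equal(det_label(rec), "minor quality control issues identified")

  clean <- mk(100, 60)
  expect_equal(nrow(adapt_assembly_pair(clean$quast, clean$samtools, reg)$issues), 0L)
  depth_only <- mk(100, 15)
  expect_equal(issue_curies(adapt_assembly_pair(depth_only$quast, depth_only$samtools, reg)),
               "GENEPIO:0100570")
})

test_that("taxonomic-consensus adapter flags any disagreement, including wet-lab", {
  reg <- test_registry()
  calls <- tibble::tibble(tool = c("Mash", "Kraken2", "FastANI"),
                          version = c("2.3", "2.1.3", "1.34"),
                          taxon = rep("Salmonella enterica", 3))
  unanimous <- adapt_taxonomic_consensus(calls, reg)
  expect_equal(nrow(unanimous$issues), 0L)
  expect_equal(unanimous$methods$name, c("Mash", "Kraken2", "FastANI"))

  wetlab <- adapt_taxonomic_consensus(calls, reg, wetlab_id = "Salmonella bongori")
  expect_equal(issue_curies(wetlab), "GENEPIO:0101038")

  calls$taxon[2] <- "Salmonella bongori"
  split <- adapt_taxonomic_consensus(calls, reg)
  expect_equal(det_label(split),
               "sequence flagged for potential quality control issues")
  expect_error(adapt_taxonomic_consensus(calls[0, ], reg),
               class = "qctags_empty_input")
})

test_that("VADR adapter maps alerts, deduplicates issues, and keeps unmapped codes", {
  reg <- test_registry()
  rec <- adapt_vadr(tool_report("VADR", "1.6.3",
                                flags = c("lowsimis", "cdsstopn", "fsthicnf")), reg)
  expect_equal(issue_curies(rec),
               c("GENEPIO:0100571", "GENEPIO:0100575", "GENEPIO:0100751"))
  none <- adapt_vadr(tool_report("VADR", "1.6.3"), reg)
  expect_equal(nrow(none$determinations), 0L)
  # repeated frameshift alerts collapse to one issue, first occurrence kept
  dup <- adapt_vadr(tool_report("VADR", "1.6.3",
                                flags = c("fsthicnf", "fstlocnf", "fsthicnf")), reg)
  expect_equal(issue_curies(dup), "GENEPIO:0100751")

  expect_warning(
    odd <- adapt_vadr(tool_report("VADR", "1.6.3", flags = c("cdsstopn", "zz9")), reg),
    class = "qctags_unmapped_alert")
  expect_match(odd$details, "zz9")
})

test_that("PHoeNIx adapter passes only on an all-SUCCESS report", {
  reg <- test_registry()
  metrics <- stats::setNames(as.list(rep("SUCCESS", 27)), sprintf("m%02d", 1:27))
  ok <- adapt_phoenix(tool_report("PHoeNIx", "2.1.0", overall = "SUCCESS",
                                  metrics = metrics), reg)
  expect_equal(ok$determinations$curie, "GENEPIO:0100563")
  expect_equal(issue_curies(ok), "GENEPIO:0001619")
  expect_equal(ok$details, "Not Applicable [GENEPIO:0001619]")

  metrics$m13 <- "FAIL"
  bad <- adapt_phoenix(tool_report("PHoeNIx", "2.1.0", overall = "SUCCESS",
                                   metrics = metrics), reg)
  expect_equal(det_label(bad), "sequence failed quality control")
  expect_match(bad$details, "m13")

  expect_message(
    vac <- adapt_phoenix(tool_report("PHoeNIx", "2.1.0", overall = "SUCCESS"), reg),
    class = "qctags_note")
  expect_equal(vac$determinations$curie, "GENEPIO:0100563")
  expect_error(adapt_phoenix(tool_report("PHoeNIx", "2.1.0"), reg),
               class = "qctags_parse_error")
})

test_that("every adapter output passes strict validation with zero errors", {
  reg <- test_registry()
  for (k in 1:10) {
    rec <- run_worked_example(k, reg)
    expect_true(report_passed(validate_record(rec, reg, profile = "strict")),
                info = sprintf("example %d", k))
  }
})

test_that("worsening a metric never removes an emitted issue", {
  reg <- test_registry()
  issues_at <- function(amb) issue_curies(adapt_ncov_tools(
    tool_report("ncov-tools", "1.9.1", metrics = list(ambiguous_sites = amb)), reg))
  for (amb in 6:10) expect_true(all(issues_at(amb) %in% issues_at(amb + 1)))

  off_at <- function(f) issue_curies(adapt_kraken2(
    tool_report("Kraken2", "2.1.3",
                taxa = tibble::tibble(taxon = c("T", "other"),
                                      fraction = c(1 - f, f))), reg, "T"))
  for (f in seq(0.25, 0.8, by = 0.1)) {
    expect_true(all(off_at(f) %in% off_at(f + 0.1)))
  }
})
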