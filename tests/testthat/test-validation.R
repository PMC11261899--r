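rules_fired <- function(report) unique(report$rule_id)

test_that("R1: QC tags without a method name are an error", {
  reg <- test_registry()
  rec <- build_record(reg, issues = "low quality sequence")
  report <- validate_record(rec, reg)
  expect_false(report_passed(report))
  expect_true("R1" %in% report$rule_id[report$severity == "error"])
  # methods-only records are legal: method metadata is valuable on its own
  only <- build_record(reg, methods = "ncov-tools", versions = "1.9.1")
  expect_true(report_passed(validate_record(only, reg)))
})

test_that("R2/R3: version presence and format are best-practice warnings", {
  reg <- test_registry()
  noversion <- validate_record(build_record(reg, methods = "FastQC"), reg)
  expect_true("R2" %in% rules_fired(noversion))
  expect_true(report_passed(noversion))

  odd <- validate_record(
    build_record(reg, methods = "FastQC", versions = "v0.12rc"), reg)
  expect_true("R3" %in% rules_fired(odd))
  ok_semver <- validate_record(
    build_record(reg, methods = "FastQC", versions = "0.12.0"), reg)
  ok_date <- validate_record(
    build_record(reg, methods = "FastQC", versions = "2023-05-17"), reg)
  expect_false("R3" %in% c(rules_fired(ok_semver), rules_fired(ok_date)))
  # calendar-invalid dates are not ISO dates
  expect_equal(classify_version("2023-02-30"), "other")
  expect_equal(classify_version("1.2.3"), "semver")
})

test_that("R4 fires exactly when method and version counts are nonzero and differ", {
  reg <- test_registry()
  # enumeration oracle over list-length pairs up to 3
  for (n_m in 1:3) {
    for (n_v in 0:3) {
      rec <- build_record(reg,
        methods = paste0("tool", seq_len(n_m)),
        versions = if (n_v > 0) rep("1.0.0", n_v) else NULL)
      fired <- "R4" %in% rules_fired(validate_record(rec, reg))
      expect_equal(fired, n_v > 0 && n_v != n_m,
                   info = sprintf("methods=%d versions=%d", n_m, n_v))
    }
  }
  mismatch <- validate_record(
    build_record(reg, methods = c("A tool", "B tool"), versions = "1.0.0"), reg)
  expect_true("R4" %in% mismatch$rule_id[mismatch$severity == "error"])
})

test_that("R5 severity tracks the profile and build_record strict output always passes it", {
  reg <- test_registry()
  rec <- build_record(reg, methods = "x", issues = "sequence exploded",
                      mode = "lenient")
  lenient <- validate_record(rec, reg, profile = "lenient")
  strict <- validate_record(rec, reg, profile = "strict")
  expect_equal(lenient$severity[lenient$rule_id == "R5"], "warning")
  expect_equal(strict$severity[strict$rule_id == "R5"], "error")
  set.seed(11)
  for (i in 1:10) {
    r <- validate_record(random_record(), reg, profile = "strict")
    expect_false("R5" %in% rules_fired(r))
  }
})

test_that("R6 notes duplicates, R9 flags Not Applicable mixed with other values", {
  reg <- test_registry()
  dup <- build_record(reg, methods = "x", versions = "1.0.0",
                      determinations = "sequence failed quality control",
                      issues = c("low quality sequence", "GENEPIO:0100568"))
  rep <- validate_record(dup, reg)
  expect_true("R6" %in% rules_fired(rep))
  expect_equal(rep$severity[rep$rule_id == "R6"], "info")

  mixed <- build_record(reg, methods = "x", versions = "1.0.0",
                        determinations = "sequence failed quality control",
                        issues = c("Not Applicable", "low quality sequence"))
  expect_true("R9" %in% rules_fired(validate_record(mixed, reg)))
  sole <- build_record(reg, methods = "x", versions = "1.0.0",
                       determinations = "sequence passed quality control",
                       issues = "Not Applicable", details = "Not Applicable")
  expect_false("R9" %in% rules_fired(validate_record(sole, reg)))
})

test_that("R7: synthetic constructs must not carry inherited sample metadata", {
  reg <- test_registry()
  bad <- build_record(reg, methods = "ncov-tools", versions = "1.9.1",
                      specimen_role = "synthetic lab construct",
                      specimen_details = "variant mix",
                      extras = c(host = "Homo sapiens", amplicon_size = "400"))
  rep <- validate_record(bad, reg)
  expect_false(report_passed(rep))
  expect_true("R7" %in% rep$rule_id[rep$severity == "error"])
  expect_match(rep$message[rep$rule_id == "R7"], "host")

  ok <- build_record(reg, methods = "ncov-tools", versions = "1.9.1",
                     specimen_role = "synthetic lab construct",
                     extras = c(amplicon_size = "400"))
  expect_true(report_passed(validate_record(ok, reg)))
})

test_that("R8 flags category misplacement and contradictory not-performed records", {
  reg <- test_registry()
  cross <- build_record(reg, methods = "x", versions = "1.0.0",
                        issues = "sequence flagged for potential quality control issues",
                        mode = "lenient")
  rep <- validate_record(cross, reg)
  expect_true("R8" %in% rules_fired(rep))
  expect_true(report_passed(rep))  # warning, not error

  contradiction <- build_record(reg, methods = "x", versions = "1.0.0",
                                determinations = "quality control not performed",
                                issues = "low quality sequence")
  expect_true("R8" %in% rules_fired(validate_record(contradiction, reg)))
})

test_that("worked examples 1-10 validate error-free; 11 warns only on category placement", {
  reg <- test_registry()
  for (k in 1:10) {
    rep <- validate_record(run_worked_example(k, reg), reg, profile = "strict")
    expect_true(report_passed(rep), info = sprintf("example %d", k))
  }
  rep11 <- validate_record(run_worked_example(11, reg), reg, profile = "strict")
  expect_true(report_passed(rep11))
  expect_equal(unique(rep11$rule_id), "R8")
  expect_equal(unique(rep11$severity), "warning")
})

test_that("strict never reports fewer findings than lenient, and validation is pure", {
  reg <- test_registry()
  set.seed(23)
  shapes <- c(lapply(1:8, function(i) random_record()),
              list(build_record(reg, issues = "low quality sequence"),
                   build_record(reg, methods = "x", issues = "boom", mode = "lenient")))
  for (rec in shapes) {
    l <- validate_record(rec, reg, profile = "lenient")
    s <- validate_record(rec, reg, profile = "strict")
    expect_gte(nrow(s), nrow(l))
    expect_identical(tibble::as_tibble(validate_record(rec, reg)),
                     tibble::as_tibble(validate_record(rec, reg)))
  }
})

test_that("collection validation aggregates per-record reports", {
  reg <- test_registry()
  coll <- worked_example_collection(reg)
  vset <- validate_collection(coll, reg, profile = "lenient")
  expect_length(vset$reports, 11L)
  expect_true(all(vset$passed))
  expect_true(all(c("rule_id", "severity", "n") %in% names(vset$summary)))

  empty <- validate_collection(qc_collection(), reg)
  expect_length(empty$reports, 0L)

  with_bad <- qc_collection(c(coll$records,
    list(build_record(reg, issues = "low quality sequence"))))
  vset2 <- validate_collection(with_bad, reg)
  expect_equal(sum(!vset2$passed), 1L)
  expect_equal(vset2$summary$n[vset2$summary$rule_id == "R1"], 1L)
  g <- glance(vset2)
  expect_equal(g$n_records, 12L)
})

test_that("rule severities are deployment-overridable", {
  reg <- test_registry()
  rec <- build_record(reg, methods = "FastQC", versions = "v0.12rc")
  rep <- validate_record(rec, reg, severity_overrides = c(R3 = "info"))
  expect_equal(rep$severity[rep$rule_id == "R3"], "info")
})
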