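# Core vocabulary: the published (label, CURIE) pairs resolve in both
# directions and render in the "label [CURIE]" convention.

CORE_PAIRS <- tibble::tribble(
  ~label, ~curie, ~category,
  "quality control method name",    "GENEPIO:0100557", "field",
  "quality control method version", "GENEPIO:0100558", "field",
  "quality control determination",  "GENEPIO:0100559", "field",
  "quality control issues",         "GENEPIO:0100560", "field",
  "quality control details",        "GENEPIO:0100561", "field",
  "no quality control issues identified",   "GENEPIO:0100562", "determination",
  "sequence passed quality control",        "GENEPIO:0100563", "determination",
  "sequence failed quality control",        "GENEPIO:0100564", "determination",
  "minor quality control issues identified", "GENEPIO:0100565", "determination",
  "sequence flagged for potential quality control issues", "GENEPIO:0100566", "determination",
  "quality control not performed",          "GENEPIO:0100567", "determination",
  "low quality sequence",                   "GENEPIO:0100568", "issue",
  "sequence contaminated",                  "GENEPIO:0100569", "issue",
  "low average genome coverage",            "GENEPIO:0100570", "issue",
  "low percent genome captured",            "GENEPIO:0100571", "issue",
  "read lengths shorter than expected",     "GENEPIO:0100572", "issue",
  "sequence amplification artefacts",       "GENEPIO:0100573", "issue",
  "low signal to noise ratio",              "GENEPIO:0100574", "issue",
  "low coverage of characteristic mutations", "GENEPIO:0100575", "issue",
  "excess frameshift mutations detected",   "GENEPIO:0100751", "issue",
  "taxonomic designation inconsistent across methods", "GENEPIO:0101038", "issue",
  "Not Applicable",                         "GENEPIO:0001619", "misc",
  "synthetic lab construct",                "GENEPIO:0101039", "misc"
)

test_that("all 23 core label/CURIE pairs resolve bidirectionally", {
  reg <- test_registry()
  expect_equal(nrow(CORE_PAIRS), 23L)
  for (i in seq_len(nrow(CORE_PAIRS))) {
    by_label <- resolve_label(reg, CORE_PAIRS$label[i])
    expect_equal(by_label$curie, CORE_PAIRS$curie[i], info = CORE_PAIRS$label[i])
    expect_equal(by_label$category, CORE_PAIRS$category[i])
    by_curie <- resolve_curie(reg, CORE_PAIRS$curie[i])
    expect_equal(by_curie$label, CORE_PAIRS$label[i], info = CORE_PAIRS$curie[i])
  }
  # plus the two CURIE-less specimen fields
  expect_true(is.na(resolve_label(reg, "experimental specimen role type")$curie))
  expect_true(is.na(resolve_label(reg, "experimental specimen details")$curie))
  expect_false(anyDuplicated(reg$curie[!is.na(reg$curie)]) > 0)
})

test_that("label resolution is case-insensitive and synonym-aware", {
  reg <- test_registry()
  expect_equal(resolve_label(reg, "LOW QUALITY SEQUENCE", "issue")$curie,
               "GENEPIO:0100568")
  # worked-example spelling resolves via synonym to the same term
  syn <- resolve_label(reg, "sequenced contaminated", "issue")
  canon <- resolve_label(reg, "sequence contaminated", "issue")
  expect_equal(syn$curie, canon$curie)
  expect_equal(syn$label, canon$label)
  # "not performed" shorthand
  expect_equal(resolve_label(reg, "not performed", "determination")$curie,
               "GENEPIO:0100567")
  # category restricts the search space
  expect_error(resolve_label(reg, "low quality sequence", "determination"),
               class = "qctags_unknown_term")
})

test_that("unknown labels error with a nearest-label suggestion", {
  reg <- test_registry()
  err <- expect_error(resolve_label(reg, "low qualty sequence", "issue"),
                      class = "qctags_unknown_term")
  expect_equal(err$suggestion, "low quality sequence")
  expect_match(conditionMessage(err), "New Term Request")
  expect_error(resolve_label(reg, "  "), class = "qctags_unknown_term")
})

test_that("CURIE resolution pads the local part and rejects unknowns", {
  reg <- test_registry()
  expect_equal(resolve_curie(reg, "GENEPIO:0100570")$label,
               "low average genome coverage")
  expect_equal(resolve_curie(reg, "GENEPIO:1619")$label, "Not Applicable")
  expect_error(resolve_curie(reg, "GENEPIO:9999999"), class = "qctags_unknown_term")
  expect_error(resolve_curie(reg, "not-a-curie"), class = "qctags_malformed_token")
})

test_that("render_term emits label [CURIE] and roundtrips through resolution", {
  reg <- test_registry()
  expect_equal(render_term(resolve_curie(reg, "GENEPIO:0100566")),
               "sequence flagged for potential quality control issues [GENEPIO:0100566]")
  expect_equal(render_term(resolve_curie(reg, "GENEPIO:0101039")),
               "synthetic lab construct [GENEPIO:0101039]")
  # resolve_label . render_term . resolve_curie is the identity on every term
  for (i in seq_len(nrow(reg))) {
    term <- reg[i, ]
    tok <- parse_term_string(render_term(term))
    back <- if (!is.na(tok$curie)) resolve_curie(reg, tok$curie)
            else resolve_label(reg, tok$label)
    expect_equal(back$label, term$label)
    expect_equal(back$curie, term$curie)
  }
})

test_that("extension terms register, participate in lookups, and reject duplicates", {
  reg <- test_registry()
  ext <- register_extension(reg, "significant quality control issues", "determination")
  term <- resolve_label(ext, "Significant Quality Control Issues", "determination")
  expect_equal(term$provenance, "extension")
  expect_true(is.na(term$curie))
  expect_equal(render_term(term), "significant quality control issues")
  # a GenomeTrakr-style record now validates cleanly
  rec <- build_record(ext, methods = "GalaxyTrakr SSQuAWK", versions = "1.0.4",
                      determinations = "significant quality control issues",
                      issues = "low signal to noise ratio", mode = "strict")
  expect_true(report_passed(validate_record(rec, ext, profile = "strict")))
  # same label is still unknown in the unextended registry
  expect_error(resolve_label(reg, "significant quality control issues"),
               class = "qctags_unknown_term")
  expect_error(register_extension(ext, "Low Quality Sequence", "issue"),
               class = "qctags_conflict")
  # synonyms of existing terms are also conflicts
  expect_error(register_extension(reg, "sequenced contaminated", "issue"),
               class = "qctags_conflict")
})
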