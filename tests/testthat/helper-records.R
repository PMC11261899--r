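# Shared fixtures: a memoised registry and a randomized strictly-valid
# record sampler used by the roundtrip property tests.

test_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- qc_term_registry()
    reg
  }
})

# Draw one record whose shape varies (method count, version style, term
# counts, specimen fields, extras) but which always validates without
# errors, so the repository writers accept it.
random_record <- function(registry = test_registry()) {
  det_pool <- registry$label[registry$category == "determination"]
  issue_pool <- registry$label[registry$category == "issue"]
  words <- c("low", "input", "ct", "value", "of", "35", "contamination",
             "suspected", "rerun", "pending", "wastewater", "composite")

  n_methods <- sample(1:3, 1)
  methods <- sample(qc_method_names(), n_methods)
  versions <- vapply(seq_len(n_methods), function(i) {
    switch(sample(3, 1),
           sprintf("%d.%d.%d", sample(0:9, 1), sample(0:20, 1), sample(0:9, 1)),
           sprintf("2023-%02d-%02d", sample(12, 1), sample(28, 1)),
           paste0("build-", sample(999, 1)))
  }, character(1))

  n_det <- sample(0:2, 1)
  n_iss <- sample(0:3, 1)
  dets <- if (n_det > 0) sample(det_pool, n_det) else NULL
  issues <- if (n_iss > 0) sample(issue_pool, n_iss) else NULL
  details <- if (stats::runif(1) < 0.5) {
    paste(sample(words, sample(3:6, 1), replace = TRUE), collapse = " ")
  } else NULL

  synthetic <- stats::runif(1) < 0.25
  extras <- if (!synthetic && stats::runif(1) < 0.4) {
    c(amplicon_size = "400", collection_site = "plant A")
  } else NULL

  build_record(
    registry,
    methods = methods, versions = versions,
    determinations = dets, issues = issues, details = details,
    specimen_role = if (synthetic) "synthetic lab construct" else NULL,
    specimen_details = if (synthetic) "spiked control mix" else NULL,
    extras = extras,
    mode = "strict"
  )
}
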