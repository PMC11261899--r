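# Condition helpers. Every user-facing failure gets a classed condition so
# callers (and the CLI) can branch on failure kind rather than message text.

abort_qc <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "qctags_error"), ...)
}

# Unknown controlled-vocabulary value: suggest the nearest registered label
# and point at the community New Term Request route.
abort_unknown_term <- function(value, candidates, field = NULL) {
  suggestion <- nearest_label(value, candidates)
  msg <- sprintf("Unknown term %s%s.", encodeString(value, quote = "'"),
                 if (is.null(field)) "" else sprintf(" in field '%s'", field))
  hints <- character()
  if (!is.na(suggestion)) {
    hints <- c(hints, sprintf("Did you mean '%s'?", suggestion))
  }
  hints <- c(hints,
    "If the vocabulary is missing a needed value, submit a New Term Request to PHA4GE (GitHub issue tracker) or register it locally with register_extension().")
  abort_qc(c(msg, stats::setNames(hints, rep("i", length(hints)))),
           class = "qctags_unknown_term",
           value = value, suggestion = suggestion)
}

nearest_label <- function(value, candidates) {
  if (length(candidates) == 0) return(NA_character_)
  d <- utils::adist(tolower(value), tolower(candidates), partial = FALSE)[1, ]
  best <- which.min(d)
  # Only suggest when the edit distance is plausibly a typo/synonym slip.
  if (d[best] <= max(3L, ceiling(nchar(value) * 0.4))) candidates[best] else NA_character_
}
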