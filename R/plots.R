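#' Plot a determination breakdown
#'
#' Horizontal bar chart of per-category counts with percentage labels,
#' mirroring the tabular pilot-style breakdown.
#'
#' @param object A `qc_breakdown` from [summarize_determinations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_breakdown <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
      x = .data$n,
      y = stats::reorder(.data$determination, .data$n))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d%%", .data$percent)),
                       hjust = -0.15, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.12))) +
    ggplot2::labs(x = "records", y = NULL,
                  title = "QC determination breakdown",
                  subtitle = sprintf("%d record(s) with determinations",
                                     attr(object, "total"))) +
    ggplot2::theme_minimal()
}

#' Plot validation findings for a collection
#'
#' Finding counts by rule and severity across a validated collection.
#'
#' @param object A `qc_validation_set` from [validate_collection()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_validation_set <- function(object, ...) {
  df <- object$summary
  if (nrow(df) == 0) {
    df <- tibble::tibble(rule_id = character(), severity = character(), n = integer())
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rule_id, y = .data$n,
                                   fill = .data$severity)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(error = "#c0392b", warning = "#e67e22",
                                          info = "#2980b9"), drop = FALSE) +
    ggplot2::labs(x = "rule", y = "findings",
                  title = "Validation findings by rule") +
    ggplot2::theme_minimal()
}
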