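#' Heatmap of a confusion matrix
#'
#' Minimal ggplot2 tile plot of the judged-vs-expected proportions, one
#' panel per scope column present (e.g. condition). Requires ggplot2.
#'
#' @param confusion Long-format confusion tibble from [confusion_long()].
#' @return A ggplot object.
#' @export
plot_confusion <- function(confusion) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_confusion requires ggplot2", call. = FALSE)
  }
  p <- ggplot2::ggplot(confusion,
                       ggplot2::aes(x = factor(.data$judged, EMOTIONS),
                                    y = factor(.data$expected, rev(EMOTIONS)),
                                    fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$proportion)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "judged", y = "expected") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(confusion)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}
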