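#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training curves
#'
#' Mean training loss and validation MRR per epoch, faceted.
#'
#' @param object A `kge_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kge_model <- function(object, ...) {
  hist <- tidyr::pivot_longer(object$history, c("loss", "valid_mrr"),
                              names_to = "metric", values_to = "value")
  hist <- hist[!is.na(hist$value), ]
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Filtered-rank distribution
#'
#' Histogram of filtered ranks by query direction.
#'
#' @param object A `kge_eval`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kge_eval <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$filtered_rank, fill = .data$direction)) +
    ggplot2::geom_histogram(bins = bins, position = "dodge") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "filtered rank", y = "queries",
                  title = "Filtered rank distribution") +
    ggplot2::theme_minimal()
}

#' Completion score distribution
#'
#' Head- and tail-direction probability histograms for scored candidate
#' triples, with the acceptance threshold marked.
#'
#' @param results Output of [kg_score_candidates()] / [kg_complete()].
#' @param threshold Threshold line to draw.
#' @param binwidth Probability bin width.
#' @return A ggplot.
#' @export
plot_completion_scores <- function(results, threshold = 0.9, binwidth = 0.05) {
  hist <- score_histogram(results, binwidth)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin, y = .data$count,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "probability", y = "candidates",
                  title = "Completion score distribution") +
    ggplot2::theme_minimal()
}
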