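## ggplot2 displays for census tables and quartet results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a census table
#'
#' Bar chart of per-topology gene counts at the table's cutoff, with
#' percentages printed above the bars and the uniform-null expectation as
#' a dashed reference line.
#'
#' @param object a `census_table`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot census_table
#' @export
autoplot.census_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  total <- attr(object, "total")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$topology, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = total / 3, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(
      title = sprintf("Gene-tree census at support > %g%%", attr(object, "cutoff") * 100),
      subtitle = sprintf("%d genes counted; dashed line = uniform null", total),
      x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot per-topology bootstrap support of a quartet result
#'
#' @param object a `quartet_result`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot quartet_result
#' @export
autoplot.quartet_result <- function(object, ...) {
  df <- tidy.quartet_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$topology, y = .data$support,
                                   fill = .data$best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "bootstrap support",
                  title = paste("Best topology:", object$best_topology)) +
    ggplot2::theme_minimal()
}

#' Plot the topology support distribution across a gene set
#'
#' Histogram of each gene's winning-topology support, faceted by best
#' topology — the distribution the census cutoffs (e.g. >50%, >70%) slice.
#'
#' @param results tibble from [infer_genes()].
#' @param bins histogram bins.
#' @return A ggplot.
#' @export
plot_support_distribution <- function(results, bins = 20) {
  sup <- as.matrix(results[, c("support_T1", "support_T2", "support_T3")])
  df <- tibble::tibble(
    best = results$best_topology,
    support = sup[cbind(seq_len(nrow(sup)),
                        match(results$best_topology, quartet_topologies()))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~best) +
    ggplot2::labs(x = "winning-topology bootstrap support", y = "genes") +
    ggplot2::theme_minimal()
}
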