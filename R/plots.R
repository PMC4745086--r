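# ggplot2 visualisations for the main result types.

#' Plot a topology report
#'
#' @param object A `topology_report` from [topology_report()].
#' @param which One of `"degree"` (log-log degree distribution with the
#'   fitted power law), `"paths"` (shortest-path length histogram) or
#'   `"tc"` (topological coefficient vs degree).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topology_report <- function(object, which = c("degree", "paths", "tc"),
                                     ...) {
  which <- match.arg(which)
  if (which == "degree") {
    dh <- dplyr::filter(object$degree_histogram, .data$k >= 1)
    dh$P <- dh$count / sum(dh$count)
    p <- ggplot2::ggplot(dh, ggplot2::aes(x = .data$k, y = .data$P)) +
      ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "degree k", y = "P(k)",
                    title = sprintf("Degree distribution (b = %.3f)",
                                    object$powerlaw_b))
    if (is.finite(object$powerlaw_b)) {
      fit <- fit_power_law(dh)
      p <- p + ggplot2::geom_line(
        ggplot2::aes(y = 10^(fit$intercept) * .data$k^(-fit$b)),
        linetype = "dashed", colour = "grey40")
    }
    p
  } else if (which == "paths") {
    ggplot2::ggplot(object$shortest_path_histogram,
                    ggplot2::aes(x = .data$distance, y = .data$count)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "shortest-path length", y = "node pairs",
                    title = "Shortest-path distribution")
  } else {
    ggplot2::ggplot(object$nodes,
                    ggplot2::aes(x = .data$degree,
                                 y = .data$topological_coefficient)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "number of neighbors",
                    y = "topological coefficient",
                    title = "Topological coefficients")
  }
}

#' MA-style plot of a differential-expression table
#'
#' Mean normalized expression against log2 fold change, coloured by call.
#'
#' @param de A tibble from [call_de()].
#' @return A ggplot object.
#' @export
plot_de <- function(de) {
  stopifnot(all(c("baseMeanA", "baseMeanB", "log2fc", "call") %in% names(de)))
  ggplot2::ggplot(de, ggplot2::aes(
    x = (.data$baseMeanA + .data$baseMeanB) / 2,
    y = .data$log2fc, colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(down = "#3366aa", unchanged = "grey70", up = "#aa3333"),
      drop = FALSE) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change (B/A)")
}

#' Dot plot of an enrichment table
#'
#' @param enrichment A tibble from [term_enrichment()].
#' @param max_terms Number of top terms (by p-value) to display.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, max_terms = 20) {
  df <- head(dplyr::arrange(enrichment, .data$pvalue), max_terms)
  df$label <- ifelse(is.na(df$term_name), df$term_id,
                     paste0(df$term_name, " (", df$term_id, ")"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$k / .data$n,
    y = stats::reorder(.data$label, -.data$pvalue),
    size = .data$k, colour = -log10(.data$qvalue))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gene ratio in set", y = NULL,
                  size = "genes", colour = "-log10 q")
}
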