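# ggplot2 visualizations for the main result types.

#' @describeIn topological_specificity distribution of topS with the
#'   degenerate 0 line marked.
#' @param object a `topology_scores` tibble.
#' @param ... unused.
#' @method autoplot topology_scores
#' @export
autoplot.topology_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$topS)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(
      x = "topological specificity (topS)", y = "genes",
      title = paste0("topS distribution",
                     if (!is.na(attr(object, "cell_type")))
                       paste0(" - ", attr(object, "cell_type")))
    )
}

#' @describeIn rwr top candidates by stationary probability.
#' @param object an `rwr_result`.
#' @param top_n candidates to display.
#' @method autoplot rwr_result
#' @export
autoplot.rwr_result <- function(object, top_n = 20, ...) {
  d <- head(filter(tidy(object), !.data$is_seed), top_n)
  d$gene <- factor(d$gene, levels = rev(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_star, y = .data$gene)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "stationary probability", y = NULL,
                  title = paste0("RWR prioritization (gamma = ",
                                 object$gamma, ")"))
}

#' @describeIn performance_and_gain null AUPRC ensemble with the true
#'   network's AUPRC marked.
#' @param object a `network_performance`.
#' @method autoplot network_performance
#' @export
autoplot.network_performance <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null_auprc)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$auprc, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "AUPRC", y = "null networks",
                  title = paste0("Recovery AUPRC vs degree-matched nulls (",
                                 object$network, ")"),
                  subtitle = paste0("performance = ",
                                    signif(object$performance, 3),
                                    ", gain = ", signif(object$gain, 3)))
}

#' Heatmap of a pairwise similarity panel
#'
#' @param panel long tibble from [similarity_panel()].
#' @param metric which column to draw: `"topology_similarity"` or
#'   `"edge_similarity"`.
#' @return a ggplot object.
#' @export
plot_similarity_matrix <- function(panel,
                                   metric = c("topology_similarity",
                                              "edge_similarity")) {
  metric <- match.arg(metric)
  nets <- sort(unique(c(panel$network_a, panel$network_b)))
  full <- bind_rows(
    select(panel, a = "network_a", b = "network_b", value = metric),
    select(panel, a = "network_b", b = "network_a", value = metric),
    tibble(a = nets, b = nets, value = 1)
  )
  ggplot2::ggplot(full, ggplot2::aes(x = .data$a, y = .data$b,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "blue",
                                  mid = "white", high = "red",
                                  name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL, title = metric) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter of topS versus tranS percentile ranks
#'
#' Highlights the genes whose network influence most exceeds their
#' expression specificity (largest `log2(PR_topS / PR_tranS)`).
#'
#' @param pr tibble from [percentile_rank_log2fc()].
#' @param highlight_n genes to label.
#' @return a ggplot object.
#' @export
plot_specificity_comparison <- function(pr, highlight_n = 5) {
  top <- head(arrange(pr, desc(.data$log2fc)), highlight_n)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$pr_tranS, y = .data$pr_topS)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         colour = "blue", se = FALSE) +
    ggplot2::geom_point(data = top, colour = "red") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "percentile rank (tranS)",
                  y = "percentile rank (topS)")
}
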