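#' Volcano plot of a differential-expression table
#'
#' Log2 fold change against -log10 p-value, colored by call direction, with
#' dashed guides at the fold-change threshold. With an exact rank test at
#' 4 vs 4 the p-values stack on the few attainable values (minimum 2/70),
#' which is visible as horizontal bands.
#'
#' @param de DE table from [call_de()].
#' @param fc_threshold Threshold used for the guide lines (default 1.5).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, fc_threshold = 1.5) {
  ggplot2::ggplot(de, ggplot2::aes(x = log2(.data$fold_change),
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_threshold), log2(fc_threshold)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            none = "grey70")) +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 p (exact Mann-Whitney)", colour = "call") +
    ggplot2::theme_minimal()
}

#' @describeIn summarize_network Degree-distribution plot of a network
#'   summary (one boxplot per degree type).
#' @param object A `cerna_network_summary`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.cerna_network_summary <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(degree = "miRNA in-degree (circRNAs)",
           value = object$mirna_degrees$in_degree),
    tibble(degree = "miRNA out-degree (mRNAs)",
           value = object$mirna_degrees$out_degree),
    tibble(degree = "mRNA in-degree (miRNAs)",
           value = object$mrna_in_degree$in_degree)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4, fill = "grey90") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "degree") +
    ggplot2::theme_minimal()
}

#' Dot plot of top enriched terms
#'
#' @param results Enrichment tibble from [enrich()].
#' @param per_namespace Top terms per namespace to show (default 5).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, per_namespace = 5) {
  top <- top_terms(results, per_namespace = per_namespace)
  if (!nrow(top)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no significant terms") +
             ggplot2::theme_void())
  }
  top$term_name <- stats::reorder(top$term_name, top$fold_enrichment)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$fold_enrichment,
                                    y = .data$term_name,
                                    size = .data$k,
                                    colour = -log10(.data$p_value))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~namespace, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "hits",
                  colour = "-log10 p") +
    ggplot2::theme_minimal()
}
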