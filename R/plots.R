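# ggplot2 figures for the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Length-distribution bar chart
#'
#' @param object A `length_distribution` from [length_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.length_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Tag length (nt)", y = "Unique tags (%)",
                  title = "Small-RNA length distribution") +
    ggplot2::theme_minimal()
}

#' Preprocessing accounting chart
#'
#' @param object An `srna_preprocess` result.
#' @param ... Unused.
#' @return A ggplot of terminal read categories.
#' @export
autoplot.srna_preprocess <- function(object, ...) {
  acc <- object$accounting[object$accounting$terminal, ]
  ggplot2::ggplot(acc, ggplot2::aes(x = stats::reorder(.data$category,
                                                       .data$reads),
                                    y = .data$reads)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Reads",
                  title = "Read accounting by terminal category") +
    ggplot2::theme_minimal()
}

#' Family-summary bar chart
#'
#' @param families Tibble from [summarize_families()].
#' @param top_n Number of families shown (default 20).
#' @return A ggplot of member counts per family.
#' @export
plot_family_summary <- function(families, top_n = 20L) {
  fam <- utils::head(families, top_n)
  ggplot2::ggplot(fam, ggplot2::aes(
      x = stats::reorder(.data$family, .data$member_count),
      y = .data$member_count)) +
    ggplot2::geom_col(fill = "sienna3") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Distinct member tags",
                  title = "Conserved miRNA families") +
    ggplot2::theme_minimal()
}

#' qPCR relative-expression bar chart
#'
#' @param object A `qpcr_result` from [relative_expression()].
#' @param ... Unused.
#' @return A ggplot with mean +/- SD error bars.
#' @export
autoplot.qpcr_result <- function(object, ...) {
  tbl <- qpcr_plot_table(object)
  ggplot2::ggplot(tbl, ggplot2::aes(
      x = stats::reorder(.data$assay_id, -.data$relative_expression),
      y = .data$relative_expression)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ymin,
                                        ymax = .data$ymax), width = 0.3) +
    ggplot2::labs(x = NULL, y = "Relative expression (vs control)",
                  title = "qPCR relative expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Network degree chart
#'
#' @param network A `mirna_network`.
#' @param top_n miRNAs shown (default 15).
#' @return A ggplot of per-miRNA target counts.
#' @export
plot_network_degree <- function(network, top_n = 15L) {
  deg <- utils::head(degree_summary(network)$mirnas, top_n)
  ggplot2::ggplot(deg, ggplot2::aes(
      x = stats::reorder(.data$mirna_id, .data$n_targets),
      y = .data$n_targets)) +
    ggplot2::geom_col(fill = "slateblue4") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Targets",
                  title = "miRNA target degree") +
    ggplot2::theme_minimal()
}
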