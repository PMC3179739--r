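# ggplot2 views of the result tables.

#' Plot a feature-diversity curve
#'
#' Non-redundant circular-fingerprint feature counts per dataset as a
#' function of fingerprint order.
#'
#' @param curve Tibble from [diversity_curve()].
#' @return A ggplot object.
#' @export
plot_diversity_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(
    x = .data$order, y = .data$n_features,
    colour = .data$dataset, group = .data$dataset
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = sort(unique(curve$order))) +
    ggplot2::labs(
      x = "Fingerprint order", y = "Non-redundant features",
      colour = "Dataset"
    ) +
    ggplot2::theme_minimal()
}

#' Plot property box plots from summary statistics
#'
#' Draws dataset-by-descriptor box plots directly from the five-number
#' summaries of [boxplot_summaries()] (no raw data needed).
#'
#' @param summaries Tibble from [boxplot_summaries()].
#' @return A ggplot object, faceted by descriptor.
#' @export
plot_property_boxes <- function(summaries) {
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$dataset)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(
        ymin = .data$min, lower = .data$q1, middle = .data$median,
        upper = .data$q3, ymax = .data$max
      ),
      stat = "identity"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$descriptor), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname dataset_similarity_matrix
#' @param object A `similarity_matrix`.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  labels <- rownames(object)
  df <- tidyr::expand_grid(dataset_a = labels, dataset_b = labels)
  df$tanimoto <- mapply(function(a, b) object[a, b], df$dataset_a, df$dataset_b)
  ggplot2::ggplot(df, ggplot2::aes(.data$dataset_a, .data$dataset_b,
    fill = .data$tanimoto
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$tanimoto)),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
      limits = c(0, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tanimoto") +
    ggplot2::theme_minimal()
}

#' @rdname scaffold_table
#' @param object A `scaffold_table`.
#' @param n Number of top scaffolds to show.
#' @export
autoplot.scaffold_table <- function(object, n = 5, ...) {
  top <- top_scaffolds(object, n)
  top$scaffold <- factor(top$scaffold, levels = rev(top$scaffold))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$pct, y = .data$scaffold)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "% of scaffold occurrences", y = NULL,
      title = sprintf("Top scaffolds: %s", attr(object, "dataset") %||% "")
    ) +
    ggplot2::theme_minimal()
}
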