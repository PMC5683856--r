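# ggplot2 layers over the result tables. The tested artifacts are the
# ordered matrices and tibbles; plots are a thin presentation layer.

#' Plot an enrichment report
#'
#' Bar chart of -log10 p per gene set, most enriched on top; the dashed
#' line marks p = 0.05.
#'
#' @param object An `enrichment_tbl` from [enrichment_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df$set_name <- stats::reorder(df$set_name, -df$p_value)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$set_name)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(
      x = expression(-log[10] ~ p), y = NULL,
      title = "Dose-effect enrichment (Welch t on log2 F)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a clustered gene-set heatmap
#'
#' Tile heatmap of per-group medians for one gene set, rows and columns
#' ordered by Spearman average-linkage clustering (see
#' [ordered_heatmap_matrix()]).
#'
#' @param exp A [dose_experiment()] or gene-by-sample matrix.
#' @param genes Gene symbols to display.
#' @param grouping Optional named sample-to-group vector.
#' @return A ggplot object.
#' @export
plot_set_heatmap <- function(exp, genes = NULL, grouping = NULL) {
  hm <- ordered_heatmap_matrix(exp, genes, grouping)
  df <- matrix_to_long(hm$values, "group")
  df$gene <- factor(df$gene, levels = rev(rownames(hm$values)))
  df$group <- factor(df$group, levels = colnames(hm$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$gene, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white", high = "#B2182B", midpoint = 0,
      name = "log2"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot bicluster coverage of the binary matrix
#'
#' Tile view of a fold-change matrix's binarized cells with the members of
#' one bicluster highlighted — a quick visual check of planted-structure
#' recovery.
#'
#' @param bin A `binary_matrix` from [binarize()].
#' @param biclusters Bicluster tibble from [bimax()].
#' @param which_bicluster Row of `biclusters` to highlight.
#' @return A ggplot object.
#' @export
plot_bicluster <- function(bin, biclusters, which_bicluster = 1L) {
  stopifnot(inherits(bin, "binary_matrix"))
  df <- matrix_to_long(bin$values, "condition")
  bc <- biclusters[biclusters$bicluster == which_bicluster, ]
  if (nrow(bc) != 1L) abort("`which_bicluster` not found")
  df$state <- dplyr::case_when(
    df$gene %in% bc$genes[[1L]] & df$condition %in% bc$conditions[[1L]] ~ "bicluster",
    df$value == 1 ~ "regulated",
    TRUE ~ "background"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$gene, fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(background = "grey95", regulated = "grey60", bicluster = "#B2182B")
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
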