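# ggplot2 displays for the main result types.

#' Plot feature frequencies per category
#'
#' Stacked percentage bars of one structural feature across fold-change
#' categories.
#'
#' @param freqs Tibble from [feature_frequencies()].
#' @param feature Feature name to display (default `"has_lacdinac"`).
#' @return A ggplot object.
#' @export
plot_feature_frequencies <- function(freqs, feature = "has_lacdinac") {
  dat <- freqs[freqs$feature == feature, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$percent,
                                    fill = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of glycopeptides", fill = feature) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot channel coordinates in PC space
#'
#' @param pca Result of [pca_glycopeptides()].
#' @return A ggplot object with channels labelled by group.
#' @export
plot_pca <- function(pca) {
  ev <- round(100 * pca$explained_variance[1:2], 1)
  ggplot2::ggplot(pca$coordinates,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$group, label = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = paste0("PC1 (", ev[1], "%)"),
                  y = paste0("PC2 (", ev[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Heatmap of clustered log2 fold changes
#'
#' @param clustering Result of [cluster_fold_changes()].
#' @return A ggplot tile heatmap in the clustered row/column order.
#' @export
plot_fold_change_heatmap <- function(clustering) {
  mat <- clustering$matrix
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(mat, rownames = "row"),
                  row = factor(.data$row, levels = rev(rownames(mat)))),
    -"row", names_to = "comparison", values_to = "log2fc"
  )
  df$comparison <- factor(df$comparison, levels = colnames(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$row,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal()
}
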