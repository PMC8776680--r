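# ggplot2 views of the main result types.

#' @describeIn composition_pca Scatter of groups on two principal components.
#' @param object A `codh_pca`.
#' @param pcs Which components to plot (default PC1/PC2).
#' @export
autoplot.codh_pca <- function(object, pcs = c("PC1", "PC2"), ...) {
  stopifnot(all(pcs %in% names(object$scores)))
  vf <- object$variance_fraction
  labs <- sprintf("%s (%.0f%%)", pcs,
                  100 * vf[as.integer(sub("PC", "", pcs))])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[pcs[1]]], .data[[pcs[2]]],
                               label = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}

#' Stacked composition bars per group
#'
#' @param profiles Output of [clade_composition()].
#' @return A ggplot object.
#' @export
plot_composition <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(.data$group, .data$fraction, fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of clusters", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise Dice coefficients
#'
#' @param dice_tbl Output of [pairwise_dice()].
#' @return A ggplot object.
#' @export
plot_dice <- function(dice_tbl) {
  ggplot2::ggplot(dice_tbl,
                  ggplot2::aes(.data$label_a, .data$label_b, fill = .data$dice)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$dice)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Dice") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
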