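# Figure helpers mirroring the standard importance-matrix visualisations:
# bar chart of factor contributions, per-class box plot of factor scores,
# and a PCA biplot with the most variable features drawn as arrows. All
# return ggplot objects; writing to disk is left to the caller.

utils::globalVariables(c("feature", "contribution", "class_label", "score",
                         "PC1", "PC2", "xend", "yend"))

#' Bar chart of the top feature contributions of an NMF factor
#'
#' @param fit An `nmf_result`.
#' @param factor Factor index (default: the discriminative factor).
#' @param n_top Number of features shown (default 15).
#' @return A ggplot object.
#' @export
plot_factor_contributions <- function(fit, factor = fit$discriminative_factor,
                                      n_top = 15L) {
  v <- top_contributions(fit, factor, n_top)
  df <- data.frame(feature = factor(names(v), levels = rev(names(v))),
                   contribution = as.numeric(v))
  ggplot2::ggplot(df, ggplot2::aes(x = feature, y = contribution)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "relative contribution", x = NULL,
                  title = paste0("Factor ", factor, " composition")) +
    ggplot2::theme_minimal()
}

#' Box plot of NMF factor sample scores by class
#'
#' @param fit An `nmf_result`.
#' @param labels 0/1 labels aligned to the rows of W.
#' @param factor Factor index (default: the discriminative factor).
#' @return A ggplot object.
#' @export
plot_factor_scores <- function(fit, labels, factor = fit$discriminative_factor) {
  df <- data.frame(score = fit$W[, factor],
                   class_label = factor(ifelse(as.numeric(labels) == 1, "A", "B")))
  ggplot2::ggplot(df, ggplot2::aes(x = class_label, y = score, fill = class_label)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "class", y = paste0("factor ", factor, " score")) +
    ggplot2::theme_minimal()
}

#' PCA biplot of an importance matrix ordination
#'
#' Sample scores on the first two axes, with loading arrows for the top-q
#' most variable features overlaid.
#'
#' @param ord An `"ordination"`.
#' @param labels Optional 0/1 labels for colouring.
#' @param q How many of the most variable features to draw (default 5).
#' @param arrow_scale Multiplier applied to the loading arrows.
#' @return A ggplot object.
#' @export
plot_biplot <- function(ord, labels = NULL, q = 5L, arrow_scale = NULL) {
  if (ncol(ord$scores) < 2L) stop("biplot needs at least 2 axes", call. = FALSE)
  df <- data.frame(PC1 = ord$scores[, 1], PC2 = ord$scores[, 2])
  df$class_label <- if (is.null(labels)) "sample" else
    factor(ifelse(as.numeric(labels) == 1, "A", "B"))
  top <- names(sort(ord$feature_variance, decreasing = TRUE))[seq_len(q)]
  L <- ord$loadings[top, 1:2, drop = FALSE]
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(df$PC1), abs(df$PC2)) / max(abs(L), 1e-12)
  }
  arr <- data.frame(feature = rownames(L),
                    xend = L[, 1] * arrow_scale, yend = L[, 2] * arrow_scale)
  pct <- round(100 * ord$explained_variance_ratio[1:2], 1)
  ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = class_label), alpha = 0.7) +
    ggplot2::geom_segment(data = arr,
                          ggplot2::aes(x = 0, y = 0, xend = xend, yend = yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "grey30") +
    ggplot2::geom_text(data = arr,
                       ggplot2::aes(x = xend, y = yend, label = feature),
                       size = 3, vjust = -0.5) +
    ggplot2::labs(x = paste0("PC1 (", pct[1], "%)"),
                  y = paste0("PC2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}
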