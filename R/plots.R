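#' Plot PCA scores
#'
#' Scatter of two principal components coloured by group, with percent
#' variance in the axis labels.
#'
#' @param object An [pca_genotypes()] result.
#' @param pcs Which two PCs to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aim_pca <- function(object, pcs = c(1, 2), ...) {
  sc <- object$scores
  df <- tibble(
    x = sc[[paste0("PC", pcs[1])]],
    y = sc[[paste0("PC", pcs[2])]],
    group = object$meta$group
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", pcs[1], object$pct_variance[pcs[1]]),
      y = sprintf("PC%d (%.1f%%)", pcs[2], object$pct_variance[pcs[2]]),
      colour = "group"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise IBD kinship
#'
#' Log-count histogram of the pairwise kinship estimates with the family
#' threshold marked; full-sib drone pairs cluster near 0.5, unrelated pairs
#' near 0.
#'
#' @param object A [kinship_matrix()] result.
#' @param threshold Vertical reference line (default 0.30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinship_matrix <- function(object, threshold = 0.30, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$f_viterbi)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "IBD kinship (Viterbi fraction)", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Panel-validation objective plot
#'
#' Mean between-class distance against mean within-Algerian distance for
#' each panel configuration, with standard-error bars; the best panel sits
#' top-left.
#'
#' @param validation Tibble from [validate_panel_pca()] rows.
#' @return A ggplot object.
#' @export
plot_panel_validation <- function(validation) {
  ggplot2::ggplot(validation,
                  ggplot2::aes(.data$within_mean, .data$between_mean,
                               label = .data$tag)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$between_mean - .data$between_se,
      ymax = .data$between_mean + .data$between_se), width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$within_mean - .data$within_se,
      xmax = .data$within_mean + .data$within_se), height = 0) +
    ggplot2::geom_point(colour = "red", size = 2) +
    ggplot2::geom_text(vjust = -1) +
    ggplot2::labs(x = "mean within-Algerian distance",
                  y = "mean Algerian vs M/C distance") +
    ggplot2::theme_minimal()
}

#' Hybrid assignment-probability plot
#'
#' Boxplots of P(Algerian) per cross type for one experiment of a
#' [hybrid_experiment()] result.
#'
#' @param x A `hybrid_experiment` result.
#' @param experiment Which experiment's samples to draw (default "A").
#' @return A ggplot object.
#' @export
plot_hybrid_probs <- function(x, experiment = "A") {
  df <- x$samples[[experiment]]
  df$class <- factor(df$class, levels = unique(df$class))
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$p_alg)) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::labs(x = NULL, y = "P(Algerian)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
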