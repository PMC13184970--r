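# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ordination plot
#'
#' First two principal-coordinate axes with the percent variance on the
#' axis labels; points can be coloured by a grouping (ecosystem, k-means
#' cluster, season) and overlaid with fitted environmental arrows.
#'
#' @param object A [pcoa_ordination()] result.
#' @param colour Optional named vector (by sample id) used to colour points.
#' @param envfit Optional [envfit_vectors()] tibble; significant arrows
#'   (p <= `env_alpha`) are drawn.
#' @param env_alpha Significance cut-off for drawn arrows.
#' @param arrow_scale Arrow length relative to the coordinate range.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_ordination <- function(object, colour = NULL, envfit = NULL,
                                     env_alpha = 0.05, arrow_scale = 0.8, ...) {
  df <- tidy(object)
  if (!is.null(colour)) df$group <- colour[df$sample_id]
  pv <- object$percent_variance
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::geom_point(
      if (is.null(colour)) NULL else ggplot2::aes(colour = .data$group),
      size = 3) +
    ggplot2::labs(
      x = sprintf("PCoA 1 (%.1f%%)", pv[1]),
      y = sprintf("PCoA 2 (%.1f%%)", pv[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(envfit)) {
    sig <- envfit[!is.na(envfit$p) & envfit$p <= env_alpha, , drop = FALSE]
    if (nrow(sig) > 0) {
      r <- arrow_scale * min(diff(range(df$Axis1)), diff(range(df$Axis2))) / 2
      sig$xend <- sig$axis1 * sqrt(sig$r_squared) * r
      sig$yend <- sig$axis2 * sqrt(sig$r_squared) * r
      p <- p +
        ggplot2::geom_segment(
          data = sig,
          ggplot2::aes(x = 0, y = 0, xend = .data$xend, yend = .data$yend),
          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
          inherit.aes = FALSE) +
        ggplot2::geom_text(
          data = sig,
          ggplot2::aes(x = 1.08 * .data$xend, y = 1.08 * .data$yend,
                       label = .data$variable),
          colour = "purple4", size = 3, inherit.aes = FALSE)
    }
  }
  p
}

#' Distance-decay plot
#'
#' Pairwise dissimilarity against months apart, with per-month means and a
#' least-squares trend line (display only; inference rests on the Mantel
#' test).
#'
#' @param object A [distance_decay()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_decay <- function(object, ...) {
  df <- object$pairs
  df$d <- df[[object$component]]
  means <- df |>
    dplyr::group_by(.data$months_apart) |>
    dplyr::summarise(d = mean(.data$d), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$months_apart, y = .data$d)) +
    ggplot2::geom_point(colour = "grey55", alpha = 0.7) +
    ggplot2::geom_point(data = means, colour = "darkolivegreen3", size = 3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "Months apart", y = object$component) +
    ggplot2::theme_minimal()
}

#' Stacked bars of dynamic-class percentages over time
#'
#' @param fractions Result of [dynamics_fractions()].
#' @return A ggplot object.
#' @export
plot_dynamics_fractions <- function(fractions) {
  fractions$class <- factor(fractions$class,
                            levels = c("sporadic", "intermittent", "persistent"))
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$timepoint, y = .data$percent,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of detected vOTUs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Effect-size bar plot of category contrasts
#'
#' Horizontal bars of the included categories' median differences, with
#' significance stars from the FDR-adjusted p-values.
#'
#' @param contrast Result of [effect_size_contrast()].
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(contrast) {
  df <- contrast[contrast$included, , drop = FALSE]
  if (nrow(df) == 0) abort("no included categories to plot.")
  df$stars <- dplyr::case_when(df$p_adjusted < 0.001 ~ "***",
                               df$p_adjusted < 0.01 ~ "**",
                               df$p_adjusted < 0.05 ~ "*",
                               TRUE ~ "")
  df$category <- stats::reorder(df$category, df$effect_size)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect_size, y = .data$category)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), hjust = -0.2) +
    ggplot2::labs(
      x = sprintf("Effect size (%s - %s, percentage points)",
                  df$group_a[1], df$group_b[1]),
      y = NULL) +
    ggplot2::theme_minimal()
}

#' Alpha-diversity comparison boxplots
#'
#' @param alpha Result of [alpha_diversity()].
#' @param groups Named group label per sample.
#' @param metric Column of `alpha` to display.
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(alpha, groups, metric = "richness_per_gb") {
  alpha$group <- groups[alpha$sample_id]
  ggplot2::ggplot(alpha, ggplot2::aes(x = .data$group, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outliers = FALSE, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Draw a clustered log-abundance heatmap
#'
#' Renders a [heatmap_matrix()] with pheatmap when available, otherwise
#' with base `image()`, preserving the computed row order.
#'
#' @param hm A [heatmap_matrix()] result.
#' @param ... Passed to `pheatmap::pheatmap()`.
#' @return The plotting object, invisibly.
#' @export
plot_heatmap <- function(hm, ...) {
  stopifnot(inherits(hm, "heatmap_matrix"))
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    invisible(pheatmap::pheatmap(hm$values, cluster_rows = FALSE,
                                 cluster_cols = FALSE, ...))
  } else {
    graphics::image(t(hm$values[rev(seq_len(nrow(hm$values))), , drop = FALSE]))
    invisible(NULL)
  }
}
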