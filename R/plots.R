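#' Plot a multiple-threshold slope curve
#'
#' Shows the richness-effect slope across the threshold grid, with the
#' pointwise standard-error band, significant thresholds emphasized, and
#' `t_min` / `t_mde` marked. The visual analogue of the curve summarized by
#' [glance.threshold_curve()].
#'
#' @param object A `threshold_curve` from [multiple_threshold_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_curve <- function(object, ...) {
  curve <- object$curve
  curve$significant <- curve$slope > 0 & curve$p < object$alpha
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$threshold_pct,
                                           y = .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$slope - .data$se,
                                      ymax = .data$slope + .data$se),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey40"),
                                 name = paste0("p < ", object$alpha,
                                               ", slope > 0")) +
    ggplot2::labs(
      x = "Threshold (% of function maximum)",
      y = "Slope (functions per unit richness)",
      title = if (!is.null(object$domain)) {
        paste0("Multiple-threshold analysis (", object$domain, ")")
      } else {
        "Multiple-threshold analysis"
      }
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$t_min)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t_min,
                                 linetype = "dotted") +
      ggplot2::annotate("text", x = object$t_min, y = max(curve$slope),
                        label = paste0("T[min] == ", object$t_min),
                        parse = TRUE, hjust = -0.1, size = 3)
  }
  p + ggplot2::geom_vline(xintercept = object$t_mde, linetype = "dotted",
                          colour = "#0072B2") +
    ggplot2::annotate("text", x = object$t_mde, y = min(curve$slope),
                      label = paste0("T[mde] == ", object$t_mde),
                      parse = TRUE, hjust = -0.1, size = 3,
                      colour = "#0072B2")
}

#' Plot rarity-category composition
#'
#' Side-by-side bars of each category's share of OTUs and of total relative
#' abundance, the standard summary of a six-category rarity classification.
#'
#' @param object A `rarity_classification` from [classify_rarity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rarity_classification <- function(object, ...) {
  s <- tidyr::pivot_longer(
    object$summary,
    c("otu_fraction_pct", "abundance_fraction_pct"),
    names_to = "measure", values_to = "pct"
  )
  s$measure <- factor(s$measure,
                      levels = c("otu_fraction_pct", "abundance_fraction_pct"),
                      labels = c("% of OTUs", "% of relative abundance"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$category, y = .data$pct,
                                  fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("#0072B2", "#E69F00"),
                               name = NULL) +
    ggplot2::labs(
      x = NULL, y = "Percent",
      title = if (!is.null(object$domain)) {
        paste0("Rarity categories (", object$domain, ")")
      } else {
        "Rarity categories"
      },
      subtitle = paste0("abundant >= ", 100 * object$abundant_threshold,
                        "%, rare < ", 100 * object$rare_threshold, "%")
    ) +
    ggplot2::theme_minimal()
}
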