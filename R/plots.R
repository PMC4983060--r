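#' Histogram of measured 25(OH)D in a biospecimen panel
#'
#' Frequency distribution of measured plasma 25(OH)D with the conventional
#' clinical cut points marked: 20 ng/mL (deficiency) and 30 ng/mL
#' (insufficiency).
#'
#' @param panel A biospecimen tibble from [sample_biospecimen_panel()] (any
#'   data frame with a `measured_25ohd` column works).
#' @param binwidth Histogram bin width in ng/mL.
#' @return A ggplot object.
#' @export
plot_panel_distribution <- function(panel, binwidth = 2.5) {
  ggplot2::ggplot(panel, ggplot2::aes(x = .data$measured_25ohd)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(20, 30), linetype = "dashed") +
    ggplot2::labs(x = "Measured 25(OH)D (ng/mL)", y = "Specimens",
                  title = "Measured plasma 25(OH)D",
                  subtitle = "Dashed lines: deficiency (20) and insufficiency (30) cut points") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of IRRs by exposure quartile
#'
#' Point estimates and 95% confidence intervals for the incidence rate
#' ratio of each predicted-25(OH)D quartile (quartile 4, highest, is the
#' reference at IRR 1).
#'
#' @param x A `vitd_cox` fit from [fit_cox()].
#' @return A ggplot object.
#' @export
plot_quartile_irr <- function(x) {
  stopifnot(inherits(x, "vitd_cox"))
  b <- x$by_quartile
  b$quartile <- factor(b$quartile, levels = 4:1)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$quartile, y = .data$irr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Predicted 25(OH)D quartile (4 = highest, reference)",
                  y = "Incidence rate ratio (95% CI)",
                  title = sprintf("Breast cancer IRR by predicted 25(OH)D quartile (%s)",
                                  x$spec$outcome)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot vitd_cox
#' @export
autoplot.vitd_cox <- function(object, ...) plot_quartile_irr(object)

#' @method autoplot cv_performance
#' @export
autoplot.cv_performance <- function(object, ...) {
  df <- tidyr::expand_grid(predicted = 1:4, observed = 1:4)
  df$prop <- as.numeric(object$agreement)  # column-major: observed fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$prop))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "Predicted quartile", y = "Observed quartile",
                  title = "Quartile cross-classification (pooled test folds)") +
    ggplot2::theme_minimal()
}
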