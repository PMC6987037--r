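# Figures: per-batch boxplots, pairwise scatter with the y = x reference,
# and Bland-Altman relative-difference plots.

#' Per-batch boxplots of method measurements
#'
#' One box per batch and method, on a log10 count-per-gram axis, faceted
#' by strain.
#'
#' @param data A measurement table.
#' @param methods Methods to draw.
#' @return A ggplot object.
#' @export
plot_method_boxplot <- function(data,
                                methods = c("Plate", "PCR.live",
                                            "Flow.live")) {
  validate_measurement_table(data)
  d <- data %>%
    filter(.data$method %in% methods, !is.na(.data$count_per_g)) %>%
    mutate(method = factor(.data$method, levels = DROPCOUNT_METHODS))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$batch_id,
                                  y = .data$count_per_g,
                                  fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(. ~ strain, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Batch", y = "Count per gram", fill = "Method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 5))
}

pair_means <- function(data, method_x, method_y) {
  mx <- batch_means(data, method_x)
  my <- batch_means(data, method_y)
  inner_join(mx, my, by = c("batch_id", "strain"),
             suffix = c("_x", "_y")) %>%
    filter(!is.na(.data$mean_count_x), !is.na(.data$mean_count_y))
}

#' Scatter plot of two methods with the identity reference
#'
#' Per-batch means of `method_y` against `method_x`, the y = x reference
#' line (dashed) and the least-squares trend (blue).
#'
#' @inheritParams plot_method_boxplot
#' @param method_x,method_y Method labels; `method_x` is the abscissa.
#' @return A ggplot object.
#' @export
plot_method_scatter <- function(data, method_x, method_y) {
  d <- pair_means(data, method_x, method_y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_count_x,
                                  y = .data$mean_count_y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.7) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$strain), size = 1.8) +
    ggplot2::labs(x = paste0(method_x, " (count/g)"),
                  y = paste0(method_y, " (count/g)"), colour = "Strain") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of two methods
#'
#' Relative differences `(x - y) / pair mean * 100` against the pair
#' means, with the mean relative difference (solid) and limits of
#' agreement (dashed).
#'
#' @inheritParams plot_method_scatter
#' @param loa_multiplier Limits-of-agreement multiplier (1.96 = 95%).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(data, method_x, method_y,
                              loa_multiplier = 1.96) {
  d <- pair_means(data, method_x, method_y) %>%
    mutate(
      avg = (.data$mean_count_x + .data$mean_count_y) / 2,
      rel_diff = (.data$mean_count_x - .data$mean_count_y) / .data$avg * 100
    )
  ba <- bland_altman(d$mean_count_x, d$mean_count_y, loa_multiplier)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$rel_diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = ba$mean_rel_diff_pct,
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low_pct, ba$loa_high_pct),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$strain), size = 1.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Pair mean (count/g)",
      y = sprintf("(%s - %s) / mean, %%", method_x, method_y),
      colour = "Strain"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.consistency_summary <- function(object, stratum = "All", ...) {
  d <- as_tibble(unclass(object)) %>%
    filter(.data$stratum == !!stratum) %>%
    mutate(method = factor(.data$method, levels = DROPCOUNT_METHODS))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method,
                                  y = .data$mean_cv_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_cv_pct - .data$sd_cv_pct, 0),
                   ymax = .data$mean_cv_pct + .data$sd_cv_pct),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "Mean per-batch CV (%)",
                  title = paste0("Method consistency (", stratum,
                                 " batches)")) +
    ggplot2::theme_minimal()
}
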