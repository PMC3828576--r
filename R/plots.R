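# ggplot2 figures for the main result types.

#' Scatter plot of a windowed correlation
#'
#' One point per window, with the pooled Pearson coefficient and its
#' significance band in the subtitle — the standard way the windowed
#' disorder/recombination/G+C relationships are displayed.
#'
#' @param stats A [window_statistics()] tibble.
#' @param xvar,yvar Columns to plot (strings).
#' @return A ggplot object.
#' @export
plot_window_correlation <- function(stats, xvar = "segment_frequency",
                                    yvar = "recombination_rate") {
  usable <- stats[!is.na(stats[[xvar]]) & !is.na(stats[[yvar]]), , drop = FALSE]
  pc <- pearson_cor(usable[[xvar]], usable[[yvar]])
  ggplot2::ggplot(usable, ggplot2::aes(.data[[xvar]], .data[[yvar]],
                                       colour = .data$chromosome)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.4) +
    ggplot2::labs(x = xvar, y = yvar,
                  subtitle = sprintf("Pearson r = %.3f (%s), n = %d windows",
                                     pc$r, pc$stars, pc$n)) +
    ggplot2::theme_minimal()
}

#' Plot conservation by chromosomal location class
#'
#' @param by_location Output of [conservation_by_location()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(by_location) {
  d <- filter(by_location, .data$n_pairs > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$location_class, .data$pct_nonconserved)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n_nonconserved,
                                                    .data$n_pairs)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% pairs with non-conserved disorder") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_disorder_model Residual diagnostics: residuals vs fitted
#'   and a normal Q-Q panel.
#' @param object A `disorder_lm` object.
#' @param ... Unused.
#' @method autoplot disorder_lm
#' @export
autoplot.disorder_lm <- function(object, ...) {
  d <- tibble(fitted = stats::fitted(object$fit),
              resid = stats::residuals(object$fit))
  qq <- stats::qqnorm(d$resid, plot.it = FALSE)
  d$tq <- qq$x
  p1 <- ggplot2::ggplot(d, ggplot2::aes(.data$fitted, .data$resid)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "fitted", y = "residual") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(d, ggplot2::aes(sample = .data$resid)) +
    ggplot2::stat_qq(alpha = 0.6) + ggplot2::stat_qq_line() +
    ggplot2::labs(x = "theoretical quantile", y = "residual") +
    ggplot2::theme_minimal()
  list(residuals_vs_fitted = p1, qq = p2)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
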