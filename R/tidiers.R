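# broom-style tidiers for the two fitted-object classes.

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a G+C enrichment test
#' @param x A `gc_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble: `estimate` (mean percentage-point difference,
#'   disordered minus ordered), `statistic`, `df`, `p.value`, `method`.
#' @method tidy gc_enrichment
#' @export
tidy.gc_enrichment <- function(x, ...) {
  tibble(estimate = x$mean_difference, statistic = x$statistic, df = x$df,
         p.value = x$p_value,
         method = if (x$paired) "paired t" else "two-sample t")
}

#' Glance at a G+C enrichment test
#' @inheritParams tidy.gc_enrichment
#' @return A one-row tibble with the test summary plus the normality check.
#' @method glance gc_enrichment
#' @export
glance.gc_enrichment <- function(x, ...) {
  tibble(estimate = x$mean_difference, statistic = x$statistic, df = x$df,
         p.value = x$p_value, n_genes = x$n_genes,
         shapiro.statistic = x$shapiro_statistic, shapiro.p = x$shapiro_p)
}

#' Tidy the disorder multiple regression
#' @param x A `disorder_lm` object from [fit_disorder_model()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, and the sequential ANOVA p-value
#'   (`anova.p`, `NA` for the intercept).
#' @method tidy disorder_lm
#' @export
tidy.disorder_lm <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4],
         anova.p = c(NA_real_, unname(x$anova_p)))
}

#' Glance at the disorder multiple regression
#' @inheritParams tidy.disorder_lm
#' @return A one-row tibble: `r.squared`, `adj.r.squared`, `n`, the two
#'   ANOVA p-values and the diagnostic statistics.
#' @method glance disorder_lm
#' @export
glance.disorder_lm <- function(x, ...) {
  tibble(r.squared = x$r_squared,
         adj.r.squared = summary(x$fit)$adj.r.squared,
         n = x$n,
         anova.p.gc = unname(x$anova_p["gc"]),
         anova.p.rec = unname(x$anova_p["rec"]),
         bp.statistic = x$bp_statistic, bp.p = x$bp_p,
         shapiro.statistic = x$shapiro_statistic, shapiro.p = x$shapiro_p)
}
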