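#' Significance bands for correlation figures
#'
#' The star convention used in the correlation figures: `***` for p < 0.005,
#' `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise. Inequalities are
#' strict, so p = 0.005 earns `**`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of bands.
#' @export
significance_band <- function(p) {
  dplyr::case_when(p < 0.005 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Pearson correlation with significance band
#'
#' Product-moment correlation with the usual t-transform p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` against the t distribution with n - 2
#' degrees of freedom, plus the figure-legend star band.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); pairs with an `NA`
#'   in either vector are dropped first.
#' @return A one-row tibble: `r`, `n`, `p`, `stars`.
#' @export
#' @examples
#' pearson_cor(1:10, (1:10) * 2 + rnorm(10, sd = 0.1))
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("need n >= 3 complete pairs")
  if (stats::sd(x) == 0) abort("zero variance in x")
  if (stats::sd(y) == 0) abort("zero variance in y")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), n = length(x), p = ct$p.value,
         stars = significance_band(ct$p.value))
}

#' Windowed correlations per chromosome and pooled
#'
#' Computes [pearson_cor()] between two columns of a window-statistics table
#' for each chromosome separately and pooled over all windows, dropping
#' windows where either value is undefined. Both the arithmetic mean of the
#' per-chromosome coefficients and the pooled coefficient are reported, since
#' a genome-level "average r" can be read either way.
#'
#' @param stats A [window_statistics()] tibble.
#' @param xvar,yvar Column names to correlate (strings), e.g.
#'   `"segment_frequency"` and `"recombination_rate"`.
#' @return A tibble with one row per chromosome plus a `"pooled"` and a
#'   `"mean_of_chromosomes"` row: `chromosome`, `r`, `n`, `p`, `stars`
#'   (`p`/`stars` are `NA` on the mean row).
#' @export
correlate_windows <- function(stats, xvar = "segment_frequency",
                              yvar = "recombination_rate") {
  usable <- stats[!is.na(stats[[xvar]]) & !is.na(stats[[yvar]]), , drop = FALSE]
  per <- usable |>
    group_by(.data$chromosome) |>
    dplyr::group_modify(~ pearson_cor(.x[[xvar]], .x[[yvar]])) |>
    ungroup()
  pooled <- pearson_cor(usable[[xvar]], usable[[yvar]]) |>
    mutate(chromosome = "pooled")
  mean_row <- tibble(chromosome = "mean_of_chromosomes", r = mean(per$r),
                     n = sum(per$n), p = NA_real_, stars = NA_character_)
  bind_rows(per, pooled, mean_row)
}

#' Index of dispersion (variance-to-mean ratio)
#'
#' Sample variance over mean of per-window counts. Equals 1 in expectation
#' under a Poisson (spatially random) placement; values above 1 indicate
#' clustering.
#'
#' @param counts Non-negative integer vector of per-window counts.
#' @return The variance-to-mean ratio.
#' @export
index_of_dispersion <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  if (all(counts == 0)) abort("all counts are zero; dispersion undefined")
  var(counts) / mean(counts)
}

#' Dispersion of disorder-containing genes along chromosomes
#'
#' Counts genes whose protein carries at least one disordered segment of
#' length >= `min_len` in fixed windows along each chromosome and returns the
#' per-chromosome variance-to-mean ratio of those counts.
#'
#' @param loci Gene loci tibble.
#' @param masks Mask tibble.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_size Fixed window size in bp (default 500000).
#' @param min_len Minimum segment length (default 30).
#' @return A tibble with columns `chromosome`, `n_windows`, `vmr`.
#' @export
disorder_dispersion <- function(loci, masks, chrom_lengths,
                                window_size = 500000, min_len = 30) {
  counts <- segment_counts(masks, min_len)
  idp <- counts$protein_id[counts$n_segments > 0]
  windows <- make_windows(chrom_lengths, "fixed", size = window_size)
  assigned <- assign_genes(windows, filter(loci, .data$protein_id %in% idp))
  per_window <- assigned |>
    filter(!is.na(.data$window)) |>
    count(.data$window)
  n_idp <- setNames(rep(0L, nrow(windows)), seq_len(nrow(windows)))
  n_idp[as.character(per_window$window)] <- per_window$n
  windows$n_idp_genes <- as.integer(n_idp)
  windows |>
    group_by(.data$chromosome) |>
    summarise(n_windows = n(), vmr = index_of_dispersion(.data$n_idp_genes),
              .groups = "drop")
}

#' Multiple regression of disorder on G+C and recombination
#'
#' Ordinary least squares fit of the per-window disordered-residue frequency
#' on the G+C-disordered frequency and the recombination rate, evaluated with
#' sequential ANOVA per-term p-values and residual diagnostics
#' (Breusch-Pagan heteroscedasticity test, Shapiro-Wilk normality test).
#' Diagnostics are reported, never used to gate the fit.
#'
#' @param stats A [window_statistics()] tibble; windows with any undefined
#'   value among the three variables are dropped.
#' @param response,gc_var,rec_var Column names of the response and the two
#'   predictors.
#' @return An object of class `disorder_lm` wrapping the [stats::lm()] fit,
#'   with `r_squared`, `anova_p` (named per-term sequential p-values),
#'   `bp_statistic`/`bp_p`, `shapiro_statistic`/`shapiro_p`, `n`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_disorder_model <- function(stats,
                               response = "disordered_residue_frequency",
                               gc_var = "gc_disordered_frequency",
                               rec_var = "recombination_rate") {
  d <- tibble(y = stats[[response]], gc = stats[[gc_var]],
              rec = stats[[rec_var]]) |>
    filter(!is.na(.data$y), !is.na(.data$gc), !is.na(.data$rec))
  if (nrow(d) <= 3L) abort("need more than 3 complete windows")
  if (qr(cbind(1, d$gc, d$rec))$rank < 3L) abort("design matrix is rank deficient")
  fit <- lm(y ~ gc + rec, data = d)
  an <- anova(fit)
  bp <- lmtest::bptest(fit)
  resid <- stats::residuals(fit)
  sh_in <- if (length(resid) > 5000) sample(resid, 5000) else resid
  sh <- shapiro.test(sh_in)
  structure(list(fit = fit,
                 n = nrow(d),
                 r_squared = summary(fit)$r.squared,
                 anova_p = setNames(an$`Pr(>F)`[1:2], c("gc", "rec")),
                 bp_statistic = unname(bp$statistic), bp_p = bp$p.value,
                 shapiro_statistic = unname(sh$statistic), shapiro_p = sh$p.value),
            class = "disorder_lm")
}

#' @export
print.disorder_lm <- function(x, ...) {
  cat("Multiple regression: disorder ~ G+C + recombination\n")
  cat(sprintf("  n = %d windows, multiple r^2 = %.3f\n", x$n, x$r_squared))
  cf <- summary(x$fit)$coefficients
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("  %-11s %+.4g (SE %.3g)\n", rownames(cf)[i], cf[i, 1], cf[i, 2]))
  }
  cat(sprintf("  ANOVA p: gc = %.3g, rec = %.3g\n", x$anova_p["gc"], x$anova_p["rec"]))
  cat(sprintf("  diagnostics: BP = %.3f (p = %.3g), Shapiro W = %.3f (p = %.3g)\n",
              x$bp_statistic, x$bp_p, x$shapiro_statistic, x$shapiro_p))
  invisible(x)
}

#' Annotation-term enrichment by hypergeometric test
#'
#' One-sided hypergeometric upper-tail test per term for over-representation
#' of the term among the study genes relative to the population, corrected
#' for the number of tested terms.
#'
#' @param study Character vector of study IDs (must be a subset of
#'   `population`).
#' @param population Character vector of population IDs.
#' @param annotations A tibble with columns `id` and `term` mapping
#'   population IDs to annotation terms.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @return A tibble sorted by ascending corrected p: `term`, `study_count`,
#'   `population_count`, `p_raw`, `p_corrected`.
#' @export
term_enrichment <- function(study, population, annotations,
                            correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  study <- unique(study); population <- unique(population)
  if (length(study) == 0L) abort("empty study set")
  if (!all(study %in% population)) abort("study IDs must be a subset of the population")
  ann <- annotations |>
    filter(.data$id %in% population) |>
    distinct(.data$id, .data$term)
  N <- length(population)
  n <- length(study)
  per_term <- ann |>
    group_by(.data$term) |>
    summarise(population_count = n(),
              study_count = sum(.data$id %in% study), .groups = "drop")
  per_term |>
    mutate(p_raw = phyper(.data$study_count - 1, .data$population_count,
                          N - .data$population_count, n, lower.tail = FALSE),
           p_corrected = p.adjust(.data$p_raw,
                                  method = if (correction == "bonferroni") "bonferroni" else "BH")) |>
    select("term", "study_count", "population_count", "p_raw", "p_corrected") |>
    arrange(.data$p_corrected, .data$p_raw)
}
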