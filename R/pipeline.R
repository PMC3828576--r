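#' Run the full disorder-recombination-G+C analysis
#'
#' Executes every stage in order on one input bundle: segment extraction,
#' the domain-relative disorder breakdown, paralogue conservation (overall
#' and by chromosomal location), per-gene G+C partitioning and the
#' enrichment test, windowed genome statistics with recombination rates,
#' Pearson correlations (disorder vs recombination, G+C vs recombination,
#' disorder vs G+C), the multiple regression, and per-chromosome dispersion
#' indices.
#'
#' @param bundle An `idr_bundle`, from [simulate_bundle()] / [read_bundle()]
#'   or assembled by hand from the individual readers.
#' @param min_len Minimum disordered-segment length in residues (default 30).
#' @param window_mode `"map"` (windows = genetic-map fragments, default) or
#'   `"fixed"`.
#' @param window_size Fixed-window size in bp (used when
#'   `window_mode = "fixed"`).
#' @return An `idr_analysis` list: `segments`, `domain_table`,
#'   `conservation`, `conservation_by_location`, `gc`, `gc_enrichment`,
#'   `window_stats`, `correlations` (list of three [correlate_windows()]
#'   tables), `regression`, `dispersion`, `exclusions` (non-fatal tallies).
#' @export
run_analysis <- function(bundle, min_len = 30, window_mode = c("map", "fixed"),
                         window_size = 500000) {
  window_mode <- match.arg(window_mode)
  check_masks_against_proteins(bundle$masks, bundle$proteins)
  segments <- extract_segments(bundle$masks, min_len)
  domain_table <- disorder_domain_table(bundle$masks, bundle$domains, bundle$loci)
  conservation <- summarize_conservation(bundle$pairs, bundle$masks, min_len)
  by_loc <- conservation_by_location(bundle$pairs, bundle$masks, bundle$loci,
                                     bundle$centromeres, bundle$chrom_lengths,
                                     min_len)
  gc <- gc_partition(bundle$cds, bundle$masks, min_len)
  gc_enrichment <- gc_enrichment_test(gc)
  windows <- make_windows(bundle$chrom_lengths, window_mode,
                          size = window_size, map = bundle$map)
  wstats <- window_statistics(windows, bundle$loci, bundle$masks, gc = gc,
                              map = bundle$map, min_len = min_len)
  correlations <- list(
    disorder_vs_rec = correlate_windows(wstats, "segment_frequency",
                                        "recombination_rate"),
    gc_vs_rec = correlate_windows(wstats, "gc_disordered_frequency",
                                  "recombination_rate"),
    disorder_vs_gc = correlate_windows(wstats, "disordered_residue_frequency",
                                       "gc_disordered_frequency"))
  regression <- fit_disorder_model(wstats)
  dispersion <- disorder_dispersion(bundle$loci, bundle$masks,
                                    bundle$chrom_lengths,
                                    window_size = window_size,
                                    min_len = min_len)
  structure(list(segments = segments, domain_table = domain_table,
                 conservation = conservation,
                 conservation_by_location = by_loc,
                 gc = gc, gc_enrichment = gc_enrichment,
                 window_stats = wstats, correlations = correlations,
                 regression = regression, dispersion = dispersion,
                 exclusions = list(
                   unassigned_genes = attr(wstats, "n_unassigned"),
                   skipped_pairs = conservation$n_skipped)),
            class = "idr_analysis")
}

#' @export
print.idr_analysis <- function(x, ...) {
  cat("idrscape analysis\n")
  cat(sprintf("  %d disordered segments across %d windows\n",
              nrow(x$segments), nrow(x$window_stats)))
  pooled <- filter(x$correlations$disorder_vs_rec, .data$chromosome == "pooled")
  cat(sprintf("  segment frequency vs recombination: pooled r = %.3f (%s)\n",
              pooled$r, pooled$stars))
  cat(sprintf("  conservation: %.1f%% of %d pairs\n",
              x$conservation$pct_conserved, x$conservation$n_pairs))
  cat(sprintf("  G+C enrichment of disordered regions: %+.2f%% (p = %.3g)\n",
              x$gc_enrichment$mean_difference, x$gc_enrichment$p_value))
  cat(sprintf("  regression r^2 = %.3f (gc p = %.3g, rec p = %.3g)\n",
              x$regression$r_squared, x$regression$anova_p["gc"],
              x$regression$anova_p["rec"]))
  invisible(x)
}

#' Compare pipeline estimates against simulation ground truth
#'
#' Runs [run_analysis()] on a simulated bundle and tabulates the estimated
#' quantities next to their generating values: the recombination coupling
#' `beta_rec` (slope of segment frequency on cM/Mb), the G+C coupling
#' `delta_gc` (slope of per-gene G+C fraction on disordered fraction),
#' per-class conservation probabilities, and the dispersion regime.
#'
#' @param bundle An `idr_bundle` carrying ground truth (from
#'   [simulate_bundle()]).
#' @param ... Passed to [run_analysis()].
#' @return A tibble with columns `quantity`, `true`, `estimated`.
#' @export
recovery_report <- function(bundle, ...) {
  if (is.null(bundle$truth) || is.null(bundle$truth$beta_rec)) {
    abort("bundle carries no ground truth; generate it with simulate_bundle()")
  }
  res <- run_analysis(bundle, ...)
  ws <- filter(res$window_stats, !is.na(.data$segment_frequency),
               !is.na(.data$recombination_rate))
  beta_hat <- unname(coef(lm(segment_frequency ~ recombination_rate, data = ws))[2])
  gd <- res$gc |>
    mutate(gc_frac = .data$gc_total / .data$gene_length,
           dis_frac = .data$disordered_length / .data$gene_length)
  delta_hat <- unname(coef(lm(gc_frac ~ dis_frac, data = gd))[2])
  cons <- res$conservation_by_location
  truth <- bundle$truth
  tibble(quantity = c("beta_rec", "delta_gc",
                      paste0("p_conserve.", cons$location_class),
                      "min_vmr_gt_1"),
         true = c(truth$beta_rec, truth$delta_gc,
                  unname(truth$p_conserve[cons$location_class]), 1),
         estimated = c(beta_hat, delta_hat, cons$pct_conserved / 100,
                       as.numeric(min(res$dispersion$vmr) > 1)))
}
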