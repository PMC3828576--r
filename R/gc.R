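#' Project a protein disorder mask onto its coding sequence
#'
#' Nucleotide `i` (0-based) of the CDS is flagged disordered iff residue
#' `floor(i/3)` lies inside an extracted disordered segment of length >=
#' `min_len`. A trailing stop codon, when present, is always ordered.
#'
#' @param calls Per-residue logical disorder calls.
#' @param cds_length CDS length in nucleotides; must be `3L` or `3L + 3`
#'   where `L = length(calls)`.
#' @param min_len Minimum segment length in residues (default 30). Use
#'   `min_len = 1` to project every disordered residue.
#' @return A logical vector of length `cds_length`.
#' @export
project_mask_to_cds <- function(calls, cds_length, min_len = 30) {
  L <- length(calls)
  if (!cds_length %in% c(3L * L, 3L * L + 3L)) {
    abort(sprintf("CDS length %d incompatible with protein length %d",
                  cds_length, L))
  }
  seg <- segment_runs(calls, min_len)
  res_flag <- rep(FALSE, L)
  for (i in seq_along(seg$start)) res_flag[(seg$start[i] + 1):seg$end[i]] <- TRUE
  nuc <- rep(res_flag, each = 3L)
  if (cds_length == 3L * L + 3L) nuc <- c(nuc, FALSE, FALSE, FALSE)
  nuc
}

#' Partition gene G+C content by disorder
#'
#' Computes, per gene, the three G+C variants: `gc_total` (G+C bases over the
#' whole CDS), `gc_disordered` (G+C bases spanning the predicted disordered
#' segments), and `gc_ordered = gc_total - gc_disordered`; plus the
#' G+C-disordered frequency `gc_disordered / gene_length` and the per-region
#' G+C percentages. `N` bases count as non-GC. Genes whose CDS length is
#' incompatible with the protein are excluded with a warning.
#'
#' @param cds A CDS tibble (`cds_id`, `sequence`), as from [read_cds_fasta()].
#' @param masks A mask tibble with matching `protein_id`s.
#' @param min_len Minimum disordered-segment length in residues (default 30).
#' @return A tibble with one row per paired gene: `gene_id`, `gene_length`
#'   (nt), `gc_total`, `gc_disordered`, `gc_ordered`,
#'   `gc_disordered_frequency`, `pct_gc_disordered_region`,
#'   `pct_gc_ordered_region` (region percentages are `NA` when the region is
#'   empty).
#' @export
gc_partition <- function(cds, masks, min_len = 30) {
  assert_mask_tbl(masks)
  lut <- mask_lookup(masks)
  have <- cds$cds_id %in% names(lut)
  if (any(!have)) {
    warn(paste0(sum(!have), " CDS record(s) without disorder mask excluded"))
  }
  cds <- cds[have, , drop = FALSE]
  m <- nrow(cds)
  ok <- logical(m)
  n_len <- n_dis_v <- gc_tot_v <- gc_dis_v <- integer(m)
  raw_g <- charToRaw("G"); raw_c <- charToRaw("C")
  for (i in seq_len(m)) {
    calls <- lut[[cds$cds_id[i]]]
    seq <- cds$sequence[i]
    nuc_flag <- tryCatch(project_mask_to_cds(calls, nchar(seq), min_len),
                         error = function(e) NULL)
    if (is.null(nuc_flag)) next
    bases <- charToRaw(seq)
    is_gc <- bases == raw_g | bases == raw_c
    ok[i] <- TRUE
    n_len[i] <- length(bases)
    n_dis_v[i] <- sum(nuc_flag)
    gc_tot_v[i] <- sum(is_gc)
    gc_dis_v[i] <- sum(is_gc & nuc_flag)
  }
  if (any(!ok)) {
    warn(paste0(sum(!ok), " gene(s) excluded: CDS/protein length mismatch"))
  }
  n <- n_len[ok]; n_dis <- n_dis_v[ok]
  gc_total <- gc_tot_v[ok]; gc_dis <- gc_dis_v[ok]
  n_ord <- n - n_dis
  tibble(gene_id = cds$cds_id[ok], gene_length = n, disordered_length = n_dis,
         gc_total = gc_total, gc_disordered = gc_dis,
         gc_ordered = gc_total - gc_dis,
         gc_disordered_frequency = gc_dis / n,
         pct_gc_disordered_region = ifelse(n_dis > 0, 100 * gc_dis / n_dis, NA_real_),
         pct_gc_ordered_region = ifelse(n_ord > 0, 100 * (gc_total - gc_dis) / n_ord,
                                        NA_real_))
}

#' Test G+C enrichment of disordered regions
#'
#' Student's t test of the per-gene difference between the G+C percentage of
#' the disordered region and that of the ordered region, over genes where
#' both regions are non-empty. The paired test (default) treats the two
#' regions of each gene as matched observations; `paired = FALSE` runs the
#' two-sample alternative. A Shapiro-Wilk statistic on the differences (or
#' pooled values) is reported alongside as the normality check.
#'
#' @param partitions Output of [gc_partition()].
#' @param paired Paired per-gene test (default) or two-sample.
#' @return An object of class `gc_enrichment`: a list with `mean_difference`
#'   (percentage points, disordered minus ordered), `statistic` (t), `df`,
#'   `p_value`, `n_genes`, `paired`, `shapiro_statistic`, `shapiro_p`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
gc_enrichment_test <- function(partitions, paired = TRUE) {
  usable <- partitions |>
    filter(!is.na(.data$pct_gc_disordered_region),
           !is.na(.data$pct_gc_ordered_region))
  if (nrow(usable) < 3L) {
    abort("need at least 3 genes with both disordered and ordered regions")
  }
  x <- usable$pct_gc_disordered_region
  y <- usable$pct_gc_ordered_region
  if (paired) {
    d <- x - y
    sh_in <- d
    if (stats::sd(d) == 0) {
      res <- list(estimate = mean(d), statistic = 0, parameter = length(d) - 1,
                  p.value = 1)
    } else {
      ht <- t.test(d)
      res <- list(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
                  parameter = unname(ht$parameter), p.value = ht$p.value)
    }
  } else {
    sh_in <- c(x - mean(x), y - mean(y))
    if (stats::sd(c(x, y)) == 0) {
      res <- list(estimate = 0, statistic = 0, parameter = length(x) + length(y) - 2,
                  p.value = 1)
    } else {
      ht <- t.test(x, y)
      res <- list(estimate = unname(ht$estimate[1] - ht$estimate[2]),
                  statistic = unname(ht$statistic),
                  parameter = unname(ht$parameter), p.value = ht$p.value)
    }
  }
  sh_in <- if (length(sh_in) > 5000) sample(sh_in, 5000) else sh_in
  sh <- if (stats::sd(sh_in) > 0) shapiro.test(sh_in) else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(mean_difference = res$estimate,
                 statistic = res$statistic,
                 df = res$parameter,
                 p_value = res$p.value,
                 n_genes = nrow(usable),
                 paired = paired,
                 shapiro_statistic = unname(sh$statistic),
                 shapiro_p = sh$p.value),
            class = "gc_enrichment")
}

#' @export
print.gc_enrichment <- function(x, ...) {
  cat(sprintf("G+C enrichment of disordered regions (%s t test)\n",
              if (x$paired) "paired" else "two-sample"))
  cat(sprintf("  mean difference: %+.2f%% (disordered - ordered), n = %d genes\n",
              x$mean_difference, x$n_genes))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g\n", x$statistic, x$df, x$p_value))
  cat(sprintf("  normality (Shapiro-Wilk): W = %.3f, p = %.3g\n",
              x$shapiro_statistic, x$shapiro_p))
  invisible(x)
}

#' Pooled and mean G+C percentage summary
#'
#' Emits both readings of a cohort-level G+C table: per-gene means of the
#' region percentages and pooled base-count percentages.
#'
#' @param partitions Output of [gc_partition()].
#' @return A tibble with columns `region`, `pct_mean_per_gene`, `pct_pooled`.
#' @export
gc_summary <- function(partitions) {
  pooled_total <- 100 * sum(partitions$gc_total) / sum(partitions$gene_length)
  dis_len <- partitions$disordered_length
  ord_len <- partitions$gene_length - dis_len
  tibble(region = c("total", "disordered", "ordered"),
         pct_mean_per_gene = c(
           mean(100 * partitions$gc_total / partitions$gene_length),
           mean(partitions$pct_gc_disordered_region, na.rm = TRUE),
           mean(partitions$pct_gc_ordered_region, na.rm = TRUE)),
         pct_pooled = c(
           pooled_total,
           100 * sum(partitions$gc_disordered) / sum(dis_len),
           100 * sum(partitions$gc_ordered) / sum(ord_len)))
}
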