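#' Is the disordered-segment count conserved within a pair?
#'
#' Two homologous proteins "conserve disorder" when they carry the same
#' number of long (>= `min_len`) disordered segments. A tolerance widens the
#' definition to counts differing by at most `count_tolerance`.
#'
#' @param calls_a,calls_b Per-residue logical disorder calls of the two
#'   proteins.
#' @param min_len Minimum segment length (default 30).
#' @param count_tolerance Maximum allowed absolute difference in segment
#'   counts still considered conserved (default 0, i.e. strict equality).
#' @return `TRUE`/`FALSE`.
#' @export
pair_is_conserved <- function(calls_a, calls_b, min_len = 30, count_tolerance = 0) {
  na <- length(segment_runs(calls_a, min_len)$start)
  nb <- length(segment_runs(calls_b, min_len)$start)
  abs(na - nb) <= count_tolerance
}

# Internal: per-pair conservation flags. Pairs with a missing mask are
# dropped with a warning and tallied in attr(, "n_skipped").
pair_conservation_flags <- function(pairs, masks, min_len = 30, count_tolerance = 0) {
  counts <- segment_counts(masks, min_len)
  lut <- setNames(counts$n_segments, counts$protein_id)
  na_ <- lut[pairs$id_a]
  nb_ <- lut[pairs$id_b]
  miss <- is.na(na_) | is.na(nb_)
  if (any(miss)) {
    warn(paste0(sum(miss), " pair(s) skipped: missing disorder mask"))
  }
  out <- pairs[!miss, , drop = FALSE]
  out$conserved <- abs(na_[!miss] - nb_[!miss]) <= count_tolerance
  attr(out, "n_skipped") <- sum(miss)
  out
}

#' Summarise disorder conservation across homologue pairs
#'
#' @param pairs A pair tibble (`id_a`, `id_b`), as from [read_pairs()].
#' @param masks A mask tibble covering the paired proteins.
#' @inheritParams pair_is_conserved
#' @return A one-row tibble: `n_pairs`, `n_conserved`, `n_nonconserved`,
#'   `pct_conserved`, `pct_nonconserved`, `n_skipped` (pairs without masks).
#' @export
summarize_conservation <- function(pairs, masks, min_len = 30, count_tolerance = 0) {
  flags <- pair_conservation_flags(pairs, masks, min_len, count_tolerance)
  if (nrow(flags) == 0L) abort("no scorable pairs (all missing masks)")
  n <- nrow(flags)
  nc <- sum(flags$conserved)
  tibble(n_pairs = n, n_conserved = nc, n_nonconserved = n - nc,
         pct_conserved = 100 * nc / n, pct_nonconserved = 100 * (n - nc) / n,
         n_skipped = attr(flags, "n_skipped"))
}

#' Classify genes by chromosomal location relative to the centromere
#'
#' Genes are placed into three location classes: `A_centromeric` when the
#' gene midpoint lies within `centromeric_radius` of the centromere (a 0.5 Mb
#' total window by default), `B_arm_proximal` when it lies within
#' `proximal_fraction` of the arm length measured from the edge of the
#' centromeric window, and `C_arm_distal` otherwise.
#'
#' @param loci Gene loci tibble (0-based half-open).
#' @param centromeres Centromere tibble (`chromosome`, `position_bp`).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param centromeric_radius Half-width of the centromeric window in bp
#'   (default 250000, i.e. a 0.5 Mb window).
#' @param proximal_fraction Fraction of the arm (measured from the
#'   centromeric window edge) labelled proximal (default 0.25).
#' @return `loci` with an added factor column `location_class`.
#' @export
classify_location <- function(loci, centromeres, chrom_lengths,
                              centromeric_radius = 250000,
                              proximal_fraction = 0.25) {
  cen <- setNames(centromeres$position_bp, centromeres$chromosome)
  missing_cen <- setdiff(unique(loci$chromosome), names(cen))
  if (length(missing_cen) > 0L) {
    abort(paste0("no centromere position for chromosome(s): ",
                 paste(missing_cen, collapse = ", ")))
  }
  mid <- floor((loci$start + loci$end) / 2)
  clen <- chrom_lengths[loci$chromosome]
  if (any(is.na(clen))) abort("chromosome in `loci` absent from `chrom_lengths`")
  if (any(mid < 0 | mid >= clen)) {
    abort("gene midpoint outside its chromosome")
  }
  cpos <- cen[loci$chromosome]
  dist <- abs(mid - cpos)
  cls <- rep("C_arm_distal", nrow(loci))
  cls[dist <= centromeric_radius] <- "A_centromeric"
  on_arm <- dist > centromeric_radius
  # arm geometry: edge of the centromeric window towards the gene
  left <- on_arm & mid < cpos
  right <- on_arm & mid >= cpos
  arm_len <- ifelse(left, pmax(cpos - centromeric_radius, 0),
                    pmax(clen - (cpos + centromeric_radius), 0))
  edge_dist <- ifelse(left, (cpos - centromeric_radius) - mid,
                      mid - (cpos + centromeric_radius))
  cls[on_arm & edge_dist <= proximal_fraction * arm_len] <- "B_arm_proximal"
  out <- loci
  out$location_class <- factor(cls, levels = c("A_centromeric", "B_arm_proximal",
                                               "C_arm_distal"))
  out
}

#' Disorder conservation stratified by chromosomal location
#'
#' Each pair is assigned the location class of its *anchor* member: `id_a`
#' when it has a gene locus on an analysed chromosome, otherwise `id_b`.
#' Pairs whose anchors fall in different classes are counted once per anchor
#' chromosome reading, i.e. under `id_a`'s class when both are placeable.
#'
#' @inheritParams summarize_conservation
#' @inheritParams classify_location
#' @return A tibble with one row per location class: `location_class` plus
#'   the [summarize_conservation()] columns (zero-pair classes have `NA`
#'   percentages).
#' @export
conservation_by_location <- function(pairs, masks, loci, centromeres,
                                     chrom_lengths, min_len = 30,
                                     count_tolerance = 0,
                                     centromeric_radius = 250000,
                                     proximal_fraction = 0.25) {
  flags <- pair_conservation_flags(pairs, masks, min_len, count_tolerance)
  placed <- classify_location(loci, centromeres, chrom_lengths,
                              centromeric_radius, proximal_fraction)
  cls <- setNames(as.character(placed$location_class), placed$protein_id)
  anchor_cls <- cls[flags$id_a]
  use_b <- is.na(anchor_cls)
  anchor_cls[use_b] <- cls[flags$id_b[use_b]]
  unplaced <- sum(is.na(anchor_cls))
  if (unplaced > 0L) {
    warn(paste0(unplaced, " pair(s) with no placeable member dropped"))
  }
  flags <- flags[!is.na(anchor_cls), , drop = FALSE]
  anchor_cls <- anchor_cls[!is.na(anchor_cls)]
  lvl <- c("A_centromeric", "B_arm_proximal", "C_arm_distal")
  per <- lapply(lvl, function(l) {
    f <- flags[anchor_cls == l, , drop = FALSE]
    n <- nrow(f); nc <- sum(f$conserved)
    tibble(location_class = l, n_pairs = n, n_conserved = nc,
           n_nonconserved = n - nc,
           pct_conserved = if (n > 0) 100 * nc / n else NA_real_,
           pct_nonconserved = if (n > 0) 100 * (n - nc) / n else NA_real_)
  })
  bind_rows(per)
}
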