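#' Build genome windows
#'
#' Fixed mode tiles each chromosome with half-open windows of `size` bp (the
#' last window truncated at the chromosome end). Map mode returns one window
#' per genetic-map interval, with identical bounds, so windowed statistics
#' line up with empirically mapped chromosome fragments.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param mode `"fixed"` or `"map"`.
#' @param size Window size in bp for fixed mode (default 500000, i.e. the
#'   0.5 Mb windows used throughout).
#' @param map Genetic-map tibble (required for map mode).
#' @return A tibble with columns `chromosome`, `start`, `end` (0-based
#'   half-open), `source`.
#' @export
make_windows <- function(chrom_lengths, mode = c("fixed", "map"), size = 500000,
                         map = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (size <= 0) abort("`size` must be positive")
    per <- lapply(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      starts <- seq(0, len - 1, by = size)
      tibble(chromosome = ch, start = starts,
             end = pmin(starts + size, len), source = "fixed")
    })
    return(bind_rows(per))
  }
  if (is.null(map)) abort("map mode requires a genetic map")
  missing_ch <- setdiff(unique(map$chromosome), names(chrom_lengths))
  if (length(missing_ch) > 0L) {
    abort(paste0("map chromosome(s) absent from `chrom_lengths`: ",
                 paste(missing_ch, collapse = ", ")))
  }
  tibble(chromosome = map$chromosome, start = map$start, end = map$end,
         source = "map_fragment")
}

#' Assign genes to windows by midpoint
#'
#' A gene belongs to the unique window containing its midpoint
#' `floor((start + end)/2)` (windows are half-open, so a midpoint sitting on
#' a boundary belongs to the upper window). In map mode the genetic map may
#' leave gaps; genes falling in a gap stay unassigned and are tallied.
#'
#' @param windows Window tibble from [make_windows()].
#' @param loci Gene loci tibble.
#' @return `loci` with an added `window` column (row index into `windows`,
#'   `NA` when unassigned); `attr(, "n_unassigned")` holds the tally.
#' @export
assign_genes <- function(windows, loci) {
  mid <- floor((loci$start + loci$end) / 2)
  win_idx <- rep(NA_integer_, nrow(loci))
  for (ch in unique(loci$chromosome)) {
    w <- which(windows$chromosome == ch)
    g <- which(loci$chromosome == ch)
    if (length(w) == 0L) next
    for (j in w) {
      inside <- mid[g] >= windows$start[j] & mid[g] < windows$end[j]
      win_idx[g[inside]] <- j
    }
  }
  out <- loci
  out$window <- win_idx
  attr(out, "n_unassigned") <- sum(is.na(win_idx))
  out
}

#' Normalise recombination rates to cM/Mb
#'
#' @param map Genetic-map tibble (`chromosome`, `start`, `end`, `cm`).
#' @return `map` with an added `recombination_rate` column, `cm` divided by
#'   the interval size in Mb.
#' @export
normalize_recombination <- function(map) {
  if (any(map$end - map$start <= 0)) abort("zero-length map interval")
  mutate(map, recombination_rate = .data$cm / ((.data$end - .data$start) / 1e6))
}

#' Per-window disorder, G+C and recombination statistics
#'
#' Aggregates per-gene quantities into windows: `n_genes`; `n_segments`
#' (disordered segments of length >= `min_len` summed over member genes);
#' `segment_frequency = n_segments / n_genes` (segments per ORF);
#' `disordered_residue_frequency` (residues inside such segments over the
#' total residues of member proteins); `gc_disordered_frequency` (summed
#' G+C-disordered bases over summed gene lengths, when `gc` is supplied);
#' and `recombination_rate` in cM/Mb for windows that coincide exactly with
#' a genetic-map interval. Windows containing zero genes have undefined
#' frequencies (`NA`) and should be excluded from correlations.
#'
#' @param windows Window tibble from [make_windows()].
#' @param loci Gene loci tibble; every locus must have a mask.
#' @param masks Mask tibble keyed by `protein_id`.
#' @param gc Optional [gc_partition()] output (keyed by `gene_id` ==
#'   `protein_id`).
#' @param map Optional genetic-map tibble used to attach recombination rates.
#' @param min_len Minimum disordered-segment length in residues (default 30).
#' @return A tibble with one row per window: `chromosome`, `start`, `end`,
#'   `source`, `n_genes`, `n_segments`, `segment_frequency`,
#'   `disordered_residue_frequency`, `gc_disordered_frequency`,
#'   `recombination_rate`; `attr(, "n_unassigned")` carries the count of
#'   genes outside every window.
#' @export
window_statistics <- function(windows, loci, masks, gc = NULL, map = NULL,
                              min_len = 30) {
  assert_mask_tbl(masks)
  missing_mask <- setdiff(loci$protein_id, masks$protein_id)
  if (length(missing_mask) > 0L) {
    abort(paste0("gene(s) without disorder mask: ",
                 paste(head(missing_mask, 5), collapse = ", ")))
  }
  assigned <- assign_genes(windows, loci)
  counts <- segment_counts(masks, min_len)
  seg <- extract_segments(masks, min_len)
  res_in_seg <- seg |>
    group_by(.data$protein_id) |>
    summarise(n_res = sum(.data$length), .groups = "drop")
  per_gene <- assigned |>
    left_join(counts, by = "protein_id") |>
    left_join(res_in_seg, by = "protein_id") |>
    mutate(n_res = dplyr::coalesce(.data$n_res, 0L),
           protein_length = lengths(masks$calls)[match(.data$protein_id,
                                                       masks$protein_id)])
  if (!is.null(gc)) {
    per_gene <- left_join(per_gene,
                          select(gc, "gene_id", "gc_disordered", "gene_length"),
                          by = c(protein_id = "gene_id"))
  } else {
    per_gene$gc_disordered <- NA_real_
    per_gene$gene_length <- NA_real_
  }
  agg <- per_gene |>
    filter(!is.na(.data$window)) |>
    group_by(.data$window) |>
    summarise(n_genes = n(),
              n_segments = sum(.data$n_segments),
              n_dis_res = sum(.data$n_res),
              n_res_total = sum(.data$protein_length),
              gc_dis = sum(.data$gc_disordered),
              nt_total = sum(.data$gene_length),
              .groups = "drop")
  out <- windows |>
    mutate(window = dplyr::row_number()) |>
    left_join(agg, by = "window") |>
    mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L),
           n_segments = dplyr::coalesce(.data$n_segments, 0L),
           segment_frequency = ifelse(.data$n_genes > 0,
                                      .data$n_segments / .data$n_genes, NA_real_),
           disordered_residue_frequency = ifelse(.data$n_genes > 0,
                                                 .data$n_dis_res / .data$n_res_total,
                                                 NA_real_),
           gc_disordered_frequency = ifelse(.data$n_genes > 0,
                                            .data$gc_dis / .data$nt_total,
                                            NA_real_)) |>
    select(-"window", -"n_dis_res", -"n_res_total", -"gc_dis", -"nt_total")
  if (!is.null(map)) {
    rates <- normalize_recombination(map) |>
      select("chromosome", "start", "end", "recombination_rate")
    out <- left_join(out, rates, by = c("chromosome", "start", "end"))
  } else {
    out$recombination_rate <- NA_real_
  }
  attr(out, "n_unassigned") <- attr(assigned, "n_unassigned")
  out
}
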