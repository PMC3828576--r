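#' Extract maximal disordered segments
#'
#' A disordered segment is a maximal run of consecutive residues predicted
#' disordered. Runs shorter than `min_len` are discarded: the analyses here
#' follow the convention that only long stretches (>= 30 residues by default)
#' count as disordered segments.
#'
#' @param masks A mask tibble with columns `protein_id` and `calls`
#'   (list-column of per-residue logicals), as from [read_disorder_masks()].
#' @param min_len Minimum segment length in residues (default 30).
#' @return A tibble with one row per retained segment: `protein_id`, `start`
#'   (0-based inclusive), `end` (exclusive), `length`, sorted by protein and
#'   start.
#' @export
#' @examples
#' m <- tibble::tibble(protein_id = "p1",
#'                     calls = list(rep(c(TRUE, FALSE), c(35, 10))))
#' extract_segments(m)
extract_segments <- function(masks, min_len = 30) {
  assert_mask_tbl(masks)
  if (min_len < 1) abort("`min_len` must be >= 1")
  runs <- lapply(masks$calls, segment_runs, min_len = min_len)
  n_per <- vapply(runs, function(r) length(r$start), integer(1))
  out <- tibble(protein_id = rep(masks$protein_id, n_per),
                start = unlist(lapply(runs, `[[`, "start"), use.names = FALSE) %||% integer(0),
                end = unlist(lapply(runs, `[[`, "end"), use.names = FALSE) %||% integer(0),
                length = unlist(lapply(runs, `[[`, "length"), use.names = FALSE) %||% integer(0))
  arrange(out, .data$protein_id, .data$start)
}

# Maximal runs of TRUE in one logical vector, as 0-based half-open intervals.
# Plain-list return: this sits in the per-protein hot path.
segment_runs <- function(calls, min_len) {
  if (length(calls) == 0L) {
    return(list(start = integer(), end = integer(), length = integer()))
  }
  r <- rle(as.logical(calls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  list(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Count disordered segments per protein
#'
#' @inheritParams extract_segments
#' @return A tibble with columns `protein_id` and `n_segments` (one row per
#'   input mask, zero counts included).
#' @export
segment_counts <- function(masks, min_len = 30) {
  assert_mask_tbl(masks)
  n <- vapply(masks$calls, function(cc) length(segment_runs(cc, min_len)$start),
              integer(1))
  tibble(protein_id = masks$protein_id, n_segments = n)
}

#' Classify disordered residues relative to annotated domains
#'
#' Overlapping domain annotations on a protein are merged (union) first. Each
#' disordered residue is then labelled `in_domain` if it falls inside a merged
#' domain, `nterm` if it lies before the first domain, `cterm` if after the
#' last, and `linker` otherwise (between two domains). Proteins without any
#' domain annotation are skipped: the classification is only defined for
#' sequences carrying both annotated domains and disorder predictions.
#'
#' @inheritParams extract_segments
#' @param domains A domain tibble (`protein_id`, `domain_id`, `start`, `end`;
#'   0-based half-open), as from [read_domains()].
#' @param min_seg_len If not `NULL`, restrict the counted disordered residues
#'   to those inside maximal segments of at least this length; the default
#'   `NULL` counts every disordered residue.
#' @return A tibble with one row per protein having >= 1 domain: columns
#'   `protein_id`, `protein_length`, `n_disordered`, `n_in_domain`,
#'   `n_linker`, `n_nterm`, `n_cterm`. The four class counts always sum to
#'   `n_disordered`.
#' @export
classify_disordered_residues <- function(masks, domains, min_seg_len = NULL) {
  assert_mask_tbl(masks)
  dsp <- split(domains, domains$protein_id)
  keep <- which(masks$protein_id %in% names(dsp))
  k <- length(keep)
  p_len <- n_dis <- n_in <- n_link <- n_nt <- n_ct <- integer(k)
  for (j in seq_len(k)) {
    id <- masks$protein_id[keep[j]]
    cc <- as.logical(masks$calls[[keep[j]]])
    d <- dsp[[id]]
    if (any(d$start < 0) || any(d$end > length(cc))) {
      abort(paste0("domain interval outside protein ", id,
                   " (length ", length(cc), ")"))
    }
    if (!is.null(min_seg_len)) {
      seg <- segment_runs(cc, min_seg_len)
      keep_res <- rep(FALSE, length(cc))
      for (i in seq_along(seg$start)) keep_res[(seg$start[i] + 1):seg$end[i]] <- TRUE
      cc <- cc & keep_res
    }
    m <- merge_intervals(d$start, d$end)
    pos <- which(cc) - 1L  # 0-based residue indices of disordered residues
    in_dom <- rep(FALSE, length(pos))
    for (i in seq_along(m$start)) {
      in_dom <- in_dom | (pos >= m$start[i] & pos < m$end[i])
    }
    nterm <- !in_dom & pos < m$start[1]
    cterm <- !in_dom & pos >= m$end[length(m$end)]
    p_len[j] <- length(cc); n_dis[j] <- length(pos)
    n_in[j] <- sum(in_dom); n_nt[j] <- sum(nterm); n_ct[j] <- sum(cterm)
    n_link[j] <- n_dis[j] - n_in[j] - n_nt[j] - n_ct[j]
  }
  tibble(protein_id = masks$protein_id[keep], protein_length = p_len,
         n_disordered = n_dis, n_in_domain = n_in, n_linker = n_link,
         n_nterm = n_nt, n_cterm = n_ct)
}

#' Summarise per-protein disorder breakdowns
#'
#' Applies the double normalisation used in the per-chromosome breakdown
#' tables: in-domain and outside-domain percentages are fractions of all
#' disordered residues, while linker/N-terminal/C-terminal percentages are
#' fractions of the *outside-domain* disordered residues (so each trio sums
#' to 100 on its own).
#'
#' @param breakdowns Output of [classify_disordered_residues()].
#' @param total_residues Total residue count of the contributing proteins
#'   (defaults to the sum of `protein_length` over `breakdowns`).
#' @return A one-row tibble: `n_proteins`, `pct_total_disorder`,
#'   `pct_in_domain`, `pct_outside`, `pct_linker`, `pct_nterm`, `pct_cterm`.
#'   Percentages that would divide by zero are `NA`.
#' @export
summarize_breakdowns <- function(breakdowns, total_residues = NULL) {
  total_residues <- total_residues %||% sum(breakdowns$protein_length)
  if (total_residues < sum(breakdowns$protein_length)) {
    abort("`total_residues` is smaller than the residues of the contributing proteins")
  }
  n_dis <- sum(breakdowns$n_disordered)
  n_in <- sum(breakdowns$n_in_domain)
  n_out <- n_dis - n_in
  n_link <- sum(breakdowns$n_linker)
  n_nt <- sum(breakdowns$n_nterm)
  n_ct <- sum(breakdowns$n_cterm)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble(n_proteins = nrow(breakdowns),
         pct_total_disorder = pct(n_dis, total_residues),
         pct_in_domain = pct(n_in, n_dis),
         pct_outside = pct(n_out, n_dis),
         pct_linker = pct(n_link, n_out),
         pct_nterm = pct(n_nt, n_out),
         pct_cterm = pct(n_ct, n_out))
}

#' Per-chromosome disorder breakdown table
#'
#' Joins the per-protein breakdowns to gene loci and summarises one row per
#' chromosome, in the shape of the per-chromosome tables of disordered-residue
#' percentages within/outside domains.
#'
#' @inheritParams classify_disordered_residues
#' @param loci Gene loci tibble (maps `protein_id` to `chromosome`).
#' @return A tibble with one row per chromosome: `chromosome` plus the
#'   [summarize_breakdowns()] columns.
#' @export
disorder_domain_table <- function(masks, domains, loci, min_seg_len = NULL) {
  br <- classify_disordered_residues(masks, domains, min_seg_len = min_seg_len)
  br <- inner_join(br, select(loci, "protein_id", "chromosome"), by = "protein_id")
  br |>
    group_by(.data$chromosome) |>
    dplyr::group_modify(~ summarize_breakdowns(.x)) |>
    ungroup() |>
    arrange(.data$chromosome)
}
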