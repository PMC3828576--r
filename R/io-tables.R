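# Tabular readers. Every file format uses 1-based inclusive coordinates;
# everything exposed by these functions is 0-based half-open. Each format is
# converted at exactly one site.

#' Read gene loci
#'
#' @param path Path to a GFF3 file or a TSV with a `#`-prefixed header and
#'   columns `gene_id`, `chromosome`, `start`, `end`, `strand`, `protein_id`
#'   (1-based inclusive coordinates).
#' @param format `"gff3"` or `"tsv"`. GFF3 keeps only rows of type `gene`;
#'   the protein ID is taken from a `protein_id` attribute, falling back to
#'   the `ID` attribute.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`
#'   (0-based half-open), `strand`, `protein_id`.
#' @export
read_gene_loci <- function(path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gff <- as.data.frame(rtracklayer::readGFF(path))
    gff <- gff[gff$type == "gene", , drop = FALSE]
    if (nrow(gff) == 0L) abort(paste0("no 'gene' rows in GFF3 file ", path))
    pid <- if ("protein_id" %in% names(gff)) gff$protein_id else gff$ID
    out <- tibble(gene_id = as.character(gff$ID),
                  chromosome = as.character(gff$seqid),
                  start = as.numeric(gff$start) - 1,
                  end = as.numeric(gff$end),
                  strand = as.character(gff$strand),
                  protein_id = as.character(pid))
  } else {
    x <- read_hash_tsv(path)
    need <- c("gene_id", "chromosome", "start", "end", "strand", "protein_id")
    if (!all(need %in% names(x))) {
      abort(paste0("gene locus TSV must have columns: ", paste(need, collapse = ", ")))
    }
    out <- tibble(gene_id = as.character(x$gene_id),
                  chromosome = as.character(x$chromosome),
                  start = as.numeric(x$start) - 1,
                  end = as.numeric(x$end),
                  strand = as.character(x$strand),
                  protein_id = as.character(x$protein_id))
  }
  if (any(out$start >= out$end)) {
    abort(paste0("gene with start >= end: ",
                 paste(head(out$gene_id[out$start >= out$end], 5), collapse = ", ")))
  }
  if (!all(out$strand %in% c("+", "-"))) {
    abort(paste0("unknown strand symbol: ",
                 paste(unique(setdiff(out$strand, c("+", "-"))), collapse = " ")))
  }
  out
}

#' Write gene loci
#'
#' @param loci A loci tibble (0-based half-open, as from [read_gene_loci()]).
#' @param path Output path.
#' @inheritParams read_gene_loci
#' @return `path`, invisibly.
#' @export
write_gene_loci <- function(loci, path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- mutate(loci, start = .data$start + 1)
    write_hash_tsv(select(out, "gene_id", "chromosome", "start", "end",
                          "strand", "protein_id"), path)
    return(invisible(path))
  }
  lines <- c("##gff-version 3",
             paste(loci$chromosome, "idrscape", "gene",
                   format(loci$start + 1, scientific = FALSE, trim = TRUE),
                   format(loci$end, scientific = FALSE, trim = TRUE),
                   ".", loci$strand, ".",
                   paste0("ID=", loci$gene_id, ";protein_id=", loci$protein_id),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genetic map
#'
#' Empirically mapped chromosome fragments with their genetic length in
#' centimorgans. Intervals on one chromosome must not overlap (touching
#' half-open intervals are fine).
#'
#' @param path TSV with `#`-prefixed header and columns `chromosome`,
#'   `start`, `end` (1-based inclusive bp), `cm`.
#' @return A tibble with columns `chromosome`, `start`, `end` (0-based
#'   half-open) and `cm`, sorted within chromosome.
#' @export
read_genetic_map <- function(path) {
  x <- read_hash_tsv(path)
  need <- c("chromosome", "start", "end", "cm")
  if (!all(need %in% names(x))) {
    abort(paste0("genetic map TSV must have columns: ", paste(need, collapse = ", ")))
  }
  out <- tibble(chromosome = as.character(x$chromosome),
                start = as.numeric(x$start) - 1,
                end = as.numeric(x$end),
                cm = as.numeric(x$cm)) |>
    arrange(.data$chromosome, .data$start)
  if (any(out$cm < 0)) abort("negative cM value in genetic map")
  if (any(out$end <= out$start)) abort("genetic map interval with end <= start")
  by_chrom <- split(out, out$chromosome)
  for (ch in names(by_chrom)) {
    b <- by_chrom[[ch]]
    if (nrow(b) > 1L) {
      ov <- which(b$start[-1] < b$end[-nrow(b)])
      if (length(ov) > 0L) {
        i <- ov[1]
        abort(sprintf(
          "overlapping genetic map intervals on %s: [%d,%d) and [%d,%d)",
          ch, b$start[i], b$end[i], b$start[i + 1], b$end[i + 1]))
      }
    }
  }
  out
}

#' Write a genetic map
#' @param map A map tibble (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  out <- mutate(map, start = .data$start + 1)
  write_hash_tsv(select(out, "chromosome", "start", "end", "cm"), path)
  invisible(path)
}

#' Read domain annotations
#'
#' Structural domain assignments (e.g. Superfamily hits) as residue intervals
#' on proteins.
#'
#' @param path TSV with `#`-prefixed header and columns `protein_id`,
#'   `domain_id`, `start`, `end` (1-based inclusive residue positions).
#' @return A tibble with columns `protein_id`, `domain_id`, `start`, `end`
#'   (0-based half-open residue intervals).
#' @export
read_domains <- function(path) {
  x <- read_hash_tsv(path)
  need <- c("protein_id", "domain_id", "start", "end")
  if (!all(need %in% names(x))) {
    abort(paste0("domain TSV must have columns: ", paste(need, collapse = ", ")))
  }
  out <- tibble(protein_id = as.character(x$protein_id),
                domain_id = as.character(x$domain_id),
                start = as.numeric(x$start) - 1,
                end = as.numeric(x$end))
  if (any(out$start >= out$end)) abort("domain with start >= end")
  if (any(out$start < 0)) abort("domain with start < 1 in input coordinates")
  out
}

#' Write domain annotations
#' @param domains A domain tibble (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains <- function(domains, path) {
  out <- mutate(domains, start = .data$start + 1)
  write_hash_tsv(select(out, "protein_id", "domain_id", "start", "end"), path)
  invisible(path)
}

#' Read paralogue/orthologue pairs
#'
#' @param path Two-column TSV (`#`-prefixed header, columns `id_a`, `id_b`).
#' @return A tibble with columns `id_a`, `id_b`.
#' @export
read_pairs <- function(path) {
  x <- read_hash_tsv(path)
  if (!all(c("id_a", "id_b") %in% names(x))) {
    abort("pair TSV must have columns id_a, id_b")
  }
  out <- tibble(id_a = as.character(x$id_a), id_b = as.character(x$id_b))
  if (any(out$id_a == out$id_b)) abort("pair with id_a == id_b")
  out
}

#' Write paralogue/orthologue pairs
#' @param pairs A pair tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  write_hash_tsv(select(pairs, "id_a", "id_b"), path)
  invisible(path)
}

#' Read centromere positions
#'
#' @param path TSV with `#`-prefixed header and columns `chromosome`,
#'   `position_bp`.
#' @return A tibble with columns `chromosome`, `position_bp`.
#' @export
read_centromeres <- function(path) {
  x <- read_hash_tsv(path)
  if (!all(c("chromosome", "position_bp") %in% names(x))) {
    abort("centromere TSV must have columns chromosome, position_bp")
  }
  tibble(chromosome = as.character(x$chromosome),
         position_bp = as.numeric(x$position_bp))
}

#' Write centromere positions
#' @param centromeres A centromere tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centromeres <- function(centromeres, path) {
  write_hash_tsv(select(centromeres, "chromosome", "position_bp"), path)
  invisible(path)
}
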