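#' Read a protein FASTA file
#'
#' Reads amino-acid sequences into a tibble, one row per record. The record ID
#' is the first whitespace-delimited token of the header; a trailing stop
#' symbol `*` is stripped from each sequence.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id`, `sequence` and `length`
#'   (residue count).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "MKLD", ">p2", "MAG*"), tf)
#' read_protein_fasta(tf)
read_protein_fasta <- function(path) {
  recs <- read_fasta_records(path)
  seqs <- toupper(sub("\\*$", "", recs$sequence))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad)) {
    abort(paste0("non-standard amino-acid letters in: ",
                 paste(head(recs$id[bad], 5), collapse = ", ")))
  }
  tibble(protein_id = recs$id, sequence = seqs, length = nchar(seqs))
}

#' Read a spliced-CDS FASTA file
#'
#' One record per protein with matching IDs; sequences are nucleotide strings
#' over A, C, G, T, N.
#'
#' @inheritParams read_protein_fasta
#' @return A tibble with columns `cds_id`, `sequence` and `length`
#'   (nucleotide count).
#' @export
read_cds_fasta <- function(path) {
  recs <- read_fasta_records(path)
  seqs <- toupper(recs$sequence)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-ACGTN letters in CDS records: ",
                 paste(head(recs$id[bad], 5), collapse = ", ")))
  }
  tibble(cds_id = recs$id, sequence = seqs, length = nchar(seqs))
}

# Shared FASTA machinery: Biostrings does the parsing, we enforce the ID and
# duplicate rules common to both readers.
read_fasta_records <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("FASTA format error in ", path, ": ",
                                                   conditionMessage(e))))
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA ID: ", paste(unique(dup), collapse = ", ")))
  }
  list(id = unname(ids), sequence = unname(as.character(set)))
}

#' Write sequences to FASTA
#'
#' @param x A tibble with an ID column (`protein_id` or `cds_id`) and a
#'   `sequence` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  id_col <- intersect(c("protein_id", "cds_id", "id"), names(x))[1]
  if (is.na(id_col)) abort("no ID column (protein_id/cds_id/id) in `x`")
  set <- Biostrings::BStringSet(setNames(x$sequence, x[[id_col]]))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Check protein/CDS pairing: CDS length must be 3L or 3L+3 (optional stop
# codon). Returns the joined tibble of compatible genes; incompatible ones are
# reported with a warning and dropped, mirroring how real proteomes carry
# annotation glitches.
pair_protein_cds <- function(proteins, cds) {
  joined <- inner_join(proteins, cds, by = c(protein_id = "cds_id"),
                       suffix = c("_aa", "_nt"))
  ok <- joined$length_nt == 3L * joined$length_aa |
    joined$length_nt == 3L * joined$length_aa + 3L
  if (any(!ok)) {
    warn(paste0(sum(!ok), " gene(s) excluded from G+C analysis: CDS length is ",
                "neither 3L nor 3L+3 of the protein (e.g. ",
                paste(head(joined$protein_id[!ok], 3), collapse = ", "), ")"))
  }
  joined[ok, , drop = FALSE]
}
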