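#' Read per-residue disorder masks
#'
#' Disorder predictions arrive either as DISOPRED-style `.diso` files (one
#' file per protein, whitespace columns `index residue mark score`, where the
#' mark is `*` for disordered and `.` for ordered) or as a FASTA-like mask
#' file with one record per protein over the two-symbol alphabet `D`
#' (disordered) / `-` (ordered).
#'
#' @param path For `mask_fasta`, the mask file; for `disopred_diso`, a
#'   directory containing `*.diso` files (protein ID = file name stem) or a
#'   character vector of `.diso` file paths.
#' @param format One of `"mask_fasta"`, `"disopred_diso"`.
#' @return A tibble with columns `protein_id` and `calls` (a list-column of
#'   logical vectors, one element per residue, `TRUE` = disordered).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "DD--D"), tf)
#' read_disorder_masks(tf)$calls[[1]]
read_disorder_masks <- function(path, format = c("mask_fasta", "disopred_diso")) {
  format <- match.arg(format)
  if (format == "mask_fasta") {
    recs <- read_fasta_records(path)
    bad <- grepl("[^D-]", recs$sequence)
    if (any(bad)) {
      abort(paste0("mask symbols other than 'D'/'-' in: ",
                   paste(head(recs$id[bad], 5), collapse = ", ")))
    }
    calls <- unname(lapply(strsplit(recs$sequence, ""), function(s) s == "D"))
    return(tibble(protein_id = recs$id, calls = calls))
  }
  files <- path
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.diso$", full.names = TRUE)
  }
  if (length(files) == 0L) abort(paste0("no .diso files found under ", path))
  out <- lapply(sort(files), read_one_diso)
  bind_rows(out)
}

read_one_diso <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) abort(paste0("empty .diso file: ", file))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L)) abort(paste0("malformed .diso line in ", file))
  idx <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 1L)))
  mark <- vapply(fields, `[[`, character(1), 3L)
  if (anyNA(idx) || !identical(idx, seq_along(idx))) {
    abort(paste0("residue numbering in ", file,
                 " is not contiguous 1..n (gap or duplicate)"))
  }
  if (!all(mark %in% c("*", "."))) {
    abort(paste0("unknown disorder mark in ", file, ": ",
                 paste(unique(setdiff(mark, c("*", "."))), collapse = " ")))
  }
  tibble(protein_id = sub("\\.diso$", "", basename(file)),
         calls = list(mark == "*"))
}

#' Write disorder masks
#'
#' @param masks A mask tibble as returned by [read_disorder_masks()].
#' @param path Output path (`mask_fasta`) or directory (`disopred_diso`).
#' @inheritParams read_disorder_masks
#' @return `path`, invisibly.
#' @export
write_disorder_masks <- function(masks, path,
                                 format = c("mask_fasta", "disopred_diso")) {
  format <- match.arg(format)
  assert_mask_tbl(masks)
  if (format == "mask_fasta") {
    seqs <- vapply(masks$calls, function(cc) paste(ifelse(cc, "D", "-"), collapse = ""),
                   character(1))
    writeLines(paste0(">", masks$protein_id, "\n", seqs), path)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (i in seq_len(nrow(masks))) {
    cc <- masks$calls[[i]]
    writeLines(paste(seq_along(cc), "X", ifelse(cc, "*", "."),
                     ifelse(cc, "0.90", "0.10")),
               file.path(path, paste0(masks$protein_id[i], ".diso")))
  }
  invisible(path)
}

# Validate mask lengths against protein lengths; error on mismatch.
check_masks_against_proteins <- function(masks, proteins) {
  lens <- setNames(proteins$length, proteins$protein_id)
  common <- intersect(masks$protein_id, names(lens))
  ml <- lengths(masks$calls)[match(common, masks$protein_id)]
  bad <- common[ml != lens[common]]
  if (length(bad) > 0L) {
    abort(paste0("mask length differs from protein length for: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(TRUE)
}
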