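# Internal helpers shared across modules.

# All TSV inputs/outputs use a single header line beginning '#', tab-separated.
read_hash_tsv <- function(path, col_types = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !startsWith(header, "#")) {
    abort(paste0("expected a '#'-prefixed header line in ", path))
  }
  cols <- strsplit(sub("^#\\s*", "", header), "\t", fixed = TRUE)[[1]]
  out <- readr::read_tsv(path, skip = 1L, col_names = cols,
                         col_types = col_types %||% readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  as_tibble(out)
}

write_hash_tsv <- function(x, path) {
  header <- paste0("#", paste(names(x), collapse = "\t"))
  body <- do.call(paste, c(lapply(x, as.character), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

# Merge possibly-overlapping half-open intervals into disjoint ones.
merge_intervals <- function(start, end) {
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  if (length(start) <= 1L) return(list(start = start, end = end))
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

assert_mask_tbl <- function(masks) {
  if (!is.data.frame(masks) || !all(c("protein_id", "calls") %in% names(masks))) {
    abort("`masks` must be a data frame with columns protein_id and calls")
  }
  invisible(masks)
}

mask_lookup <- function(masks) {
  setNames(masks$calls, masks$protein_id)
}
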