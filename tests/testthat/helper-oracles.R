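# Independent brute-force oracles and fixture builders used across tests.

# Maximal-run extraction by explicit left-to-right scan; deliberately coded
# independently of the rle-based implementation.
oracle_runs <- function(calls, min_len) {
  out <- list()
  i <- 1L
  n <- length(calls)
  while (i <= n) {
    if (calls[i]) {
      j <- i
      while (j < n && calls[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        out[[length(out) + 1L]] <- c(start = i - 1L, end = j, length = j - i + 1L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# Per-residue domain-relative labelling: membership tested against the raw
# (unmerged) annotations, termini against global extremes.
oracle_classify <- function(calls, dom_start, dom_end) {
  pos <- which(calls) - 1L
  in_dom <- vapply(pos, function(p) any(p >= dom_start & p < dom_end), logical(1))
  first <- min(dom_start)
  last <- max(dom_end)
  nterm <- !in_dom & pos < first
  cterm <- !in_dom & pos >= last
  c(n_disordered = length(pos), n_in_domain = sum(in_dom),
    n_linker = sum(!in_dom & !nterm & !cterm),
    n_nterm = sum(nterm), n_cterm = sum(cterm))
}

random_mask_tbl <- function(n_prot, len_range = c(50, 2000), p = 0.25) {
  lens <- sample(len_range[1]:len_range[2], n_prot, replace = TRUE)
  tibble::tibble(
    protein_id = sprintf("rp%04d", seq_len(n_prot)),
    calls = lapply(lens, function(L) runif(L) < p))
}

# One small simulated bundle shared by the slower integration tests.
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- idrscape::simulate_bundle(idrscape::simulation_config(
        n_pairs = 400, seed = 20260925))
    }
    cache
  }
})
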