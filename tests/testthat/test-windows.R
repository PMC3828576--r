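test_that("fixed windows tile chromosomes exactly once, last window truncated", {
  w <- make_windows(c(chr1 = 1.2e6), "fixed", size = 5e5)
  expect_equal(w$start, c(0, 5e5, 1e6))
  expect_equal(w$end, c(5e5, 1e6, 1.2e6))

  withr::local_seed(21)
  for (i in 1:20) {
    len <- sample(1e5:3e6, 1)
    size <- sample(c(1e5, 2.5e5, 5e5), 1)
    w <- make_windows(c(c1 = len), "fixed", size = size)
    expect_equal(w$start[1], 0)
    expect_equal(w$end[nrow(w)], len)
    # disjoint, adjacent coverage
    expect_equal(w$start[-1], w$end[-nrow(w)])
    expect_equal(sum(w$end - w$start), len)
  }
})

test_that("map windows coincide with genetic-map intervals", {
  map <- tibble::tibble(chromosome = "chr1", start = c(0, 2e5, 7e5),
                        end = c(2e5, 7e5, 1e6), cm = c(1, 2, 3))
  w <- make_windows(c(chr1 = 1e6), "map", map = map)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, map$start)
  expect_equal(w$end, map$end)
  expect_equal(unique(w$source), "map_fragment")
  expect_error(make_windows(c(chr2 = 1e6), "map", map = map), "absent")
})

test_that("genes are assigned by midpoint with half-open boundaries", {
  w <- make_windows(c(chr1 = 1e6), "fixed", size = 5e5)
  loci <- tibble::tibble(
    gene_id = c("g1", "g2"), chromosome = "chr1",
    start = c(100, 499900), end = c(300, 500100),  # g2 midpoint exactly 500000
    strand = "+", protein_id = c("p1", "p2"))
  a <- assign_genes(w, loci)
  expect_equal(a$window, c(1L, 2L))  # boundary midpoint goes to the upper window

  # map-mode gaps leave genes unassigned and tallied
  map <- tibble::tibble(chromosome = "chr1", start = 6e5, end = 1e6, cm = 1)
  wm <- make_windows(c(chr1 = 1e6), "map", map = map)
  am <- assign_genes(wm, loci)
  expect_true(all(is.na(am$window)))
  expect_equal(attr(am, "n_unassigned"), 2L)
})

test_that("every gene lands in at most one window", {
  withr::local_seed(22)
  w <- make_windows(c(chr1 = 2e6, chr2 = 1e6), "fixed", size = 3e5)
  starts <- sample(0:(2e6 - 2000), 300)
  loci <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                         chromosome = sample(c("chr1", "chr2"), 300, TRUE),
                         start = ifelse(sample(c(TRUE, FALSE), 300, TRUE),
                                        starts %% 1e6, starts),
                         end = 0, strand = "+",
                         protein_id = sprintf("p%03d", 1:300))
  loci$end <- loci$start + sample(500:2000, 300, TRUE)
  loci$start <- pmin(loci$start, ifelse(loci$chromosome == "chr2", 1e6 - 2001, 2e6 - 2001))
  loci$end <- loci$start + 1000
  a <- assign_genes(w, loci)
  mid <- floor((loci$start + loci$end) / 2)
  for (i in seq_len(nrow(loci))) {
    hits <- which(w$chromosome == loci$chromosome[i] &
                    w$start <= mid[i] & w$end > mid[i])
    expect_lte(length(hits), 1L)
    expect_equal(a$window[i], if (length(hits)) hits else NA_integer_)
  }
})

test_that("recombination normalisation is cM over Mb and invertible", {
  m <- tibble::tibble(chromosome = "chr1", start = 0, end = 5e5, cm = 2)
  expect_equal(normalize_recombination(m)$recombination_rate, 4)
  m0 <- tibble::tibble(chromosome = "chr1", start = 0, end = 5e5, cm = 0)
  expect_equal(normalize_recombination(m0)$recombination_rate, 0)

  withr::local_seed(23)
  starts <- cumsum(c(0, sample(1e4:1e6, 30)))
  mr <- tibble::tibble(chromosome = "chr1", start = starts[1:30],
                       end = starts[2:31], cm = runif(30, 0, 10))
  nr <- normalize_recombination(mr)
  expect_equal(nr$recombination_rate * (mr$end - mr$start) / 1e6, mr$cm)

  expect_error(normalize_recombination(
    tibble::tibble(chromosome = "c", start = 5, end = 5, cm = 1)), "zero-length")
})

test_that("window statistics aggregate per-gene quantities and conserve totals", {
  # 2 genes, 3 segments total -> segment frequency 1.5
  calls1 <- c(rep(TRUE, 35), rep(FALSE, 15), rep(TRUE, 40), rep(FALSE, 10))
  calls2 <- c(rep(FALSE, 10), rep(TRUE, 30), rep(FALSE, 60))
  masks <- tibble::tibble(protein_id = c("p1", "p2"),
                          calls = list(calls1, calls2))
  loci <- tibble::tibble(gene_id = c("g1", "g2"), chromosome = "chr1",
                         start = c(1000, 2000), end = c(1300, 2300),
                         strand = "+", protein_id = c("p1", "p2"))
  w <- make_windows(c(chr1 = 5e5), "fixed")
  ws <- window_statistics(w, loci, masks)
  expect_equal(ws$n_genes, 2L)
  expect_equal(ws$n_segments, 3L)
  expect_equal(ws$segment_frequency, 1.5)
  expect_equal(ws$disordered_residue_frequency, (35 + 40 + 30) / 200)

  # genes without disorder: zero frequencies, not NA
  masks0 <- tibble::tibble(protein_id = c("p1", "p2"),
                           calls = list(rep(FALSE, 100), rep(FALSE, 100)))
  ws0 <- window_statistics(w, loci, masks0)
  expect_equal(ws0$segment_frequency, 0)
  expect_equal(ws0$disordered_residue_frequency, 0)

  # missing mask is fatal
  expect_error(window_statistics(w, loci, masks[1, ]), "without disorder mask")

  # totals conserve across windows on a simulated genome
  b <- shared_bundle()
  w2 <- make_windows(b$chrom_lengths, "map", map = b$map)
  genome_masks <- b$masks[b$masks$protein_id %in% b$loci$protein_id, ]
  ws2 <- window_statistics(w2, b$loci, b$masks, map = b$map)
  expect_equal(sum(ws2$n_segments) ,
               nrow(extract_segments(genome_masks)))
  expect_equal(sum(ws2$n_genes) + attr(ws2, "n_unassigned"), nrow(b$loci))
  # map windows carry exact normalized rates
  nr <- normalize_recombination(b$map)
  expect_equal(ws2$recombination_rate, nr$recombination_rate)
})

test_that("empty windows are flagged undefined and excluded from correlations", {
  masks <- tibble::tibble(protein_id = "p1",
                          calls = list(c(rep(TRUE, 30), rep(FALSE, 70))))
  loci <- tibble::tibble(gene_id = "g1", chromosome = "chr1", start = 100,
                         end = 400, strand = "+", protein_id = "p1")
  w <- make_windows(c(chr1 = 1e6), "fixed", size = 5e5)
  ws <- window_statistics(w, loci, masks)
  expect_equal(ws$n_genes, c(1L, 0L))
  expect_true(is.na(ws$segment_frequency[2]))
})
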