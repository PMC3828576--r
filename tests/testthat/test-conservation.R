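seg_calls <- function(n_seg, len = 35, gap = 5, pad = 10) {
  parts <- c(list(rep(FALSE, pad)),
             rep(list(c(rep(TRUE, len), rep(FALSE, gap))), n_seg),
             list(rep(FALSE, pad)))
  unlist(parts)
}

test_that("pair conservation is strict equality of long-segment counts", {
  expect_true(pair_is_conserved(seg_calls(2), seg_calls(2)))
  expect_false(pair_is_conserved(seg_calls(0), seg_calls(1)))
  expect_true(pair_is_conserved(seg_calls(0), seg_calls(0)))  # 0 vs 0 conserved
  expect_true(pair_is_conserved(seg_calls(1), seg_calls(2), count_tolerance = 1))
})

test_that("conservation summary counts scorable pairs and tallies skips", {
  masks <- tibble::tibble(protein_id = c("a", "b", "c", "d"),
                          calls = list(seg_calls(1), seg_calls(1),
                                       seg_calls(2), seg_calls(0)))
  pairs <- tibble::tibble(id_a = c("a", "a", "c"), id_b = c("b", "c", "d"))
  s <- summarize_conservation(pairs, masks)
  expect_equal(s$n_pairs, 3L)
  expect_equal(s$n_conserved, 1L)
  expect_equal(s$pct_conserved, 100 / 3)
  expect_equal(s$pct_conserved + s$pct_nonconserved, 100)

  # missing mask: skipped with warning, tallied
  pairs2 <- dplyr::bind_rows(pairs, tibble::tibble(id_a = "a", id_b = "zz"))
  expect_warning(s2 <- summarize_conservation(pairs2, masks), "skipped")
  expect_equal(s2$n_pairs, 3L)
  expect_equal(s2$n_skipped, 1L)

  expect_error(suppressWarnings(
    summarize_conservation(tibble::tibble(id_a = "q", id_b = "r"), masks)),
    "scorable")

  # identical masks on every pair: 100% conserved
  s3 <- summarize_conservation(tibble::tibble(id_a = "a", id_b = "a2"),
                               tibble::tibble(protein_id = c("a", "a2"),
                                              calls = list(seg_calls(3), seg_calls(3))))
  expect_equal(s3$pct_conserved, 100)
})

test_that("conservation is symmetric and order-invariant", {
  withr::local_seed(31)
  masks <- random_mask_tbl(60, c(100, 600), p = 0.3)
  pairs <- tibble::tibble(id_a = masks$protein_id[1:30],
                          id_b = masks$protein_id[31:60])
  s1 <- summarize_conservation(pairs, masks)
  s2 <- summarize_conservation(tibble::tibble(id_a = pairs$id_b, id_b = pairs$id_a),
                               masks)
  s3 <- summarize_conservation(pairs[sample(30), ], masks)
  expect_equal(s1$pct_conserved, s2$pct_conserved)
  expect_equal(s1$pct_conserved, s3$pct_conserved)
})

test_that("synthetic cohort with conservation probability 0.65 is recovered at n = 5000", {
  cfg <- simulation_config(n_pairs = 5000,
                           p_conserve = c(A_centromeric = 0.65,
                                          B_arm_proximal = 0.65,
                                          C_arm_distal = 0.65),
                           seed = 77)
  b <- simulate_bundle(cfg)
  s <- summarize_conservation(b$pairs, b$masks)
  expect_lt(abs(s$pct_conserved / 100 - 0.65), 0.02)
})

test_that("location classes match direct geometric computation", {
  withr::local_seed(41)
  clen <- c(chr1 = 2e6)
  cen <- tibble::tibble(chromosome = "chr1", position_bp = 1e6)
  starts <- sample(0:(2e6 - 1000), 400)
  loci <- tibble::tibble(gene_id = sprintf("g%03d", 1:400), chromosome = "chr1",
                         start = starts, end = starts + 999,
                         strand = "+", protein_id = sprintf("p%03d", 1:400))
  got <- classify_location(loci, cen, clen)
  mid <- floor((loci$start + loci$end) / 2)
  dist <- abs(mid - 1e6)
  # direct binning: A within 250 kb; B within 25% of the 750 kb arm from the
  # window edge (i.e. dist <= 250e3 + 187.5e3); C beyond
  want <- ifelse(dist <= 250e3, "A_centromeric",
                 ifelse(dist <= 250e3 + 0.25 * 750e3, "B_arm_proximal",
                        "C_arm_distal"))
  expect_equal(as.character(got$location_class), want)
  # partition is exhaustive and exclusive
  expect_false(anyNA(got$location_class))

  # midpoint 100 kb from the centromere: A; arm tip: C
  ex <- tibble::tibble(gene_id = c("gA", "gC"), chromosome = "chr1",
                       start = c(9e5, 1999000), end = c(9e5 + 200, 1999999),
                       strand = "+", protein_id = c("pA", "pC"))
  cls <- classify_location(ex, cen, clen)
  expect_equal(as.character(cls$location_class),
               c("A_centromeric", "C_arm_distal"))
})

test_that("per-class conservation mirrors the worked 1/8 example and recovers class probabilities", {
  # toy: 8 A-type pairs of which 1 non-conserved -> 12.5% non-conserved
  masks <- tibble::tibble(
    protein_id = c(sprintf("a%d", 1:8), sprintf("b%d", 1:8)),
    calls = c(lapply(1:8, function(i) seg_calls(1)),
              lapply(1:8, function(i) seg_calls(if (i == 1) 2 else 1))))
  loci <- tibble::tibble(gene_id = sprintf("g%d", 1:8), chromosome = "chr1",
                         start = 9e5 + (1:8) * 1000, end = 9e5 + (1:8) * 1000 + 500,
                         strand = "+", protein_id = sprintf("a%d", 1:8))
  pairs <- tibble::tibble(id_a = sprintf("a%d", 1:8), id_b = sprintf("b%d", 1:8))
  cen <- tibble::tibble(chromosome = "chr1", position_bp = 1e6)
  by_loc <- conservation_by_location(pairs, masks, loci, cen, c(chr1 = 2e6))
  a_row <- by_loc[by_loc$location_class == "A_centromeric", ]
  expect_equal(a_row$n_pairs, 8L)
  expect_equal(a_row$pct_nonconserved, 12.5)
  # all pairs were A-type: other classes empty but reported
  expect_equal(by_loc$n_pairs[by_loc$location_class != "A_centromeric"], c(0L, 0L))

  # class-dependent probabilities recovered on a simulated genome
  b <- shared_bundle()
  by_loc2 <- conservation_by_location(b$pairs, b$masks, b$loci, b$centromeres,
                                      b$chrom_lengths)
  truth <- b$truth$pair_draws
  for (cl in c("B_arm_proximal", "C_arm_distal")) {
    tr <- truth[truth$location_class == cl, ]
    got <- by_loc2[by_loc2$location_class == cl, ]
    expect_equal(got$n_pairs, nrow(tr))
    expect_equal(got$pct_conserved, 100 * mean(tr$conserved))
  }
})
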