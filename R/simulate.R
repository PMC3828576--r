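# Synthetic-genome generator. Emits a complete, internally consistent input
# bundle (proteins, CDS, disorder masks, domains, gene loci, genetic map,
# centromeres, paralogue pairs) whose statistical structure matches what the
# analysis assumes: per-window recombination rates drawn from a gamma with
# multiplicative hotspots, per-gene disordered-segment counts Poisson with
# mean coupled to the window's recombination rate, coding sequences whose G+C
# rises with disordered content through disorder-prone amino acids (R/G/A/P)
# encoded by GC-rich codons, and paralogue pairs that conserve their
# segment count with a location-class-dependent probability.

#' Simulation configuration
#'
#' Ground-truth parameters of the synthetic genome. The defaults describe a
#' compact two-chromosome genome (24 windows of 0.5 Mb, 50 genes each) with
#' realistic plant-like magnitudes: window recombination rates averaging a
#' few cM/Mb with occasional hotspots, roughly 0.3 baseline long disordered
#' segments per protein rising with local recombination, and a modest G+C
#' increment in disordered coding regions.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of every chromosome (bp).
#' @param window_size_bp Fixed window / map-fragment size (bp).
#' @param genes_per_window Genes placed in each window.
#' @param mean_protein_length Mean protein length (residues).
#' @param rec_shape,rec_scale Gamma shape/scale of the per-window genetic
#'   length (cM per window).
#' @param hotspot_count Hotspot windows per chromosome.
#' @param hotspot_multiplier Multiplier applied to hotspot window cM.
#' @param lambda0 Baseline expected number of long disordered segments per
#'   protein.
#' @param beta_rec Increment in expected long-segment count per unit
#'   recombination rate (cM/Mb); 0 decouples disorder from recombination.
#' @param seg_len_min Minimum disordered-segment length (residues).
#' @param seg_len_mean_excess Mean geometric excess over `seg_len_min`.
#' @param short_run_rate Expected number of short (< `seg_len_min`)
#'   disordered runs per protein (realistic masks contain loops that never
#'   reach segment length).
#' @param gc_baseline Target G+C fraction of ordered coding sequence.
#' @param gene_gc_sd Standard deviation of the per-gene baseline G+C
#'   fraction (genes differ in background composition, so the
#'   disorder-G+C relation is noisy rather than deterministic).
#' @param delta_gc Target increase of per-gene G+C fraction per unit
#'   disordered residue fraction; 0 decouples G+C from disorder.
#' @param domains_per_protein_mean Mean annotated domains per protein
#'   (every protein gets at least one).
#' @param domain_len_mean Mean domain length (residues).
#' @param n_pairs Number of paralogue pairs to emit.
#' @param p_conserve Named probabilities (classes `A_centromeric`,
#'   `B_arm_proximal`, `C_arm_distal`) that a pair conserves its
#'   disordered-segment count.
#' @param centromeric_radius,proximal_fraction Location-class geometry (see
#'   [classify_location()]).
#' @param seed Integer seed; fully determines the emitted bundle.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_chromosomes = 2,
                              chrom_length_bp = 6e6,
                              window_size_bp = 5e5,
                              genes_per_window = 50,
                              mean_protein_length = 300,
                              rec_shape = 2, rec_scale = 2,
                              hotspot_count = 1, hotspot_multiplier = 5,
                              lambda0 = 0.3, beta_rec = 0.05,
                              seg_len_min = 30, seg_len_mean_excess = 20,
                              short_run_rate = 0.5,
                              gc_baseline = 0.45, gene_gc_sd = 0.03,
                              delta_gc = 0.08,
                              domains_per_protein_mean = 1.5,
                              domain_len_mean = 60,
                              n_pairs = 1000,
                              p_conserve = c(A_centromeric = 0.85,
                                             B_arm_proximal = 0.65,
                                             C_arm_distal = 0.65),
                              centromeric_radius = 250000,
                              proximal_fraction = 0.25,
                              seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$rec_shape, cfg$rec_scale, cfg$lambda0, cfg$beta_rec,
             cfg$short_run_rate, cfg$delta_gc)
  if (any(rates < 0)) abort("all rates must be >= 0")
  if (any(cfg$p_conserve < 0 | cfg$p_conserve > 1)) {
    abort("conservation probabilities must lie in [0, 1]")
  }
  if (cfg$gc_baseline <= 0 || cfg$gc_baseline >= 1) abort("gc_baseline must be in (0,1)")
  # infeasible segment geometry is rejected before any emission
  if (cfg$mean_protein_length < cfg$seg_len_min + 10) {
    abort("segments of `seg_len_min` cannot fit in proteins of `mean_protein_length`")
  }
  structure(cfg, class = "simulation_config")
}

# ---- codon machinery -------------------------------------------------------

codon_tables <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  aa <- unname(code[code != "*"])
  gc_frac <- vapply(strsplit(codons, ""), function(s) sum(s %in% c("G", "C")) / 3,
                    numeric(1))
  by_aa <- split(codons, aa)
  gc_by_codon <- setNames(gc_frac, codons)
  min_by_aa <- lapply(by_aa, function(cs) cs[gc_by_codon[cs] == min(gc_by_codon[cs])])
  max_by_aa <- lapply(by_aa, function(cs) cs[gc_by_codon[cs] == max(gc_by_codon[cs])])
  e_uni <- mean(vapply(by_aa, function(cs) mean(gc_by_codon[cs]), numeric(1)))
  e_min <- mean(vapply(by_aa, function(cs) min(gc_by_codon[cs]), numeric(1)))
  list(by_aa = by_aa, min_by_aa = min_by_aa, max_by_aa = max_by_aa,
       aa = sort(unique(aa)), e_uni = e_uni, e_min = e_min)
}

# Sample amino acids and codons for a vector of disorder calls. Ordered
# residues: uniform amino acid; codon drawn from a mixture of GC-minimal and
# uniform synonymous codons tuned so expected G+C hits the gene's baseline
# (per-gene baselines jitter around `gc_baseline` with sd `gene_gc_sd`).
# Disordered residues: with probability w_idr a disorder-prone amino acid
# (R/G/A/P) with its GC-maximal codon, else as ordered; w_idr is set so the
# per-gene G+C rises by ~delta_gc per unit disordered fraction.
sample_coding <- function(calls_all, owner, base_gc, cfg, tab) {
  n <- length(calls_all)
  q_min <- pmin(1, pmax(0, (tab$e_uni - base_gc[owner]) / (tab$e_uni - tab$e_min)))
  w_idr <- min(1, cfg$delta_gc / (1 - cfg$gc_baseline))
  idr_aa <- c("R", "G", "A", "P")
  aa <- sample(tab$aa, n, replace = TRUE)
  branch <- ifelse(runif(n) < q_min, "min", "uni")
  biased <- calls_all & runif(n) < w_idr
  aa[biased] <- sample(idr_aa, sum(biased), replace = TRUE)
  branch[biased] <- "max"
  codon <- character(n)
  pools <- list(min = tab$min_by_aa, max = tab$max_by_aa, uni = tab$by_aa)
  groups <- split(seq_len(n), paste0(branch, ".", aa))
  for (g in names(groups)) {
    key <- strsplit(g, ".", fixed = TRUE)[[1]]
    pool <- pools[[key[1]]][[key[2]]]
    idx <- groups[[g]]
    codon[idx] <- sample(pool, length(idx), replace = TRUE)
  }
  list(aa = aa, codon = codon)
}

# ---- mask construction -----------------------------------------------------

# Build one protein's disorder calls: n_seg long segments separated by >= 1
# ordered residue, plus sprinkled short (< seg_len_min) disordered runs that
# never touch an existing run.
build_mask <- function(n_seg, cfg) {
  seg_len <- if (n_seg > 0) {
    cfg$seg_len_min + rgeom(n_seg, 1 / (cfg$seg_len_mean_excess + 1))
  } else integer(0)
  L0 <- max(50L, round(rnorm(1, cfg$mean_protein_length, cfg$mean_protein_length / 5)))
  need <- sum(seg_len) + max(0L, n_seg - 1L) + 10L
  L <- max(L0, need)
  calls <- rep(FALSE, L)
  if (n_seg > 0) {
    free <- L - sum(seg_len) - (n_seg - 1L)  # after interior 1-gaps
    alloc <- as.vector(rmultinom(1, free, rep(1, n_seg + 1L)))
    gaps <- alloc + c(0L, rep(1L, max(0L, n_seg - 1L)), 0L)
    pos <- 0L
    for (i in seq_len(n_seg)) {
      pos <- pos + gaps[i]
      calls[(pos + 1L):(pos + seg_len[i])] <- TRUE
      pos <- pos + seg_len[i]
    }
  }
  for (k in seq_len(rpois(1, cfg$short_run_rate))) {
    len <- sample(3:10, 1)
    for (try in 1:8) {
      s <- sample.int(L - len + 1L, 1)
      lo <- max(1L, s - 1L); hi <- min(L, s + len)
      if (!any(calls[lo:hi])) {
        calls[s:(s + len - 1L)] <- TRUE
        break
      }
    }
  }
  calls
}

# Mutate a mask for a non-conserved paralogue partner: remove one long
# segment, or add one (in a wide-enough ordered gap, else by tail extension),
# so the long-segment count always changes by exactly one.
mutate_mask <- function(calls, cfg) {
  seg <- segment_runs(calls, cfg$seg_len_min)
  if (length(seg$start) > 0 && runif(1) < 0.5) {
    i <- sample.int(length(seg$start), 1)
    calls[(seg$start[i] + 1):seg$end[i]] <- FALSE
    return(calls)
  }
  new_len <- cfg$seg_len_min + rgeom(1, 1 / (cfg$seg_len_mean_excess + 1))
  gaps <- segment_runs(!calls, 1)
  fit <- which(gaps$length >= new_len + 2)
  if (length(fit) > 0) {
    gi <- fit[sample.int(length(fit), 1)]
    # 0-based start in [gap_start+1, gap_end-new_len-1]: 1 ordered margin each side
    s <- gaps$start[gi] + sample.int(gaps$length[gi] - new_len - 1, 1)
    calls[(s + 1):(s + new_len)] <- TRUE
  } else {
    calls <- c(calls, rep(FALSE, 5), rep(TRUE, new_len), rep(FALSE, 5))
  }
  calls
}

# ---- the generator ---------------------------------------------------------

#' Simulate a complete synthetic input bundle
#'
#' Generates every input the analysis consumes, together with the ground
#' truth used to produce it. The seed recorded in the configuration fully
#' determines the output.
#'
#' @param config A [simulation_config()].
#' @return An `idr_bundle` list with elements `proteins`, `cds`, `masks`,
#'   `domains`, `loci`, `map`, `centromeres`, `pairs`, `chrom_lengths`,
#'   `config` and `truth` (per-window true rates, per-gene true segment
#'   coordinates, the coupling parameters and per-pair conservation draws).
#' @export
#' @examples
#' bundle <- simulate_bundle(simulation_config(n_pairs = 50, seed = 7))
#' dplyr::glimpse(bundle$loci)
simulate_bundle <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from simulation_config()")
  }
  cfg <- config
  withr::local_seed(cfg$seed)
  tab <- codon_tables()

  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_lengths <- setNames(rep(cfg$chrom_length_bp, cfg$n_chromosomes), chroms)
  windows <- make_windows(chrom_lengths, "fixed", size = cfg$window_size_bp)
  n_w <- nrow(windows)

  cm <- rgamma(n_w, shape = cfg$rec_shape, scale = cfg$rec_scale)
  for (ch in chroms) {
    idx <- which(windows$chromosome == ch)
    hot <- sample(idx, min(cfg$hotspot_count, length(idx)))
    cm[hot] <- cm[hot] * cfg$hotspot_multiplier
  }
  rate <- cm / (cfg$window_size_bp / 1e6)
  map <- tibble(chromosome = windows$chromosome, start = windows$start,
                end = windows$end, cm = cm)

  # genes: fixed number per window, Poisson long-segment counts coupled to rate
  g_win <- rep(seq_len(n_w), each = cfg$genes_per_window)
  n_genes <- length(g_win)
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  protein_id <- sprintf("p%05d", seq_len(n_genes))
  n_seg <- rpois(n_genes, cfg$lambda0 + cfg$beta_rec * rate[g_win])
  calls_list <- lapply(n_seg, build_mask, cfg = cfg)
  masks <- tibble(protein_id = protein_id, calls = calls_list)

  # paralogue pairs need loci first for the anchor's location class
  L_aa <- lengths(calls_list)
  gene_len_bp <- 3L * L_aa + 3L
  starts <- numeric(n_genes)
  for (j in seq_len(n_w)) {
    g <- which(g_win == j)
    span <- cfg$window_size_bp - max(gene_len_bp[g]) - 1
    starts[g] <- windows$start[j] + sort(floor(runif(length(g), 0, span)))
  }
  loci <- tibble(gene_id = gene_id, chromosome = windows$chromosome[g_win],
                 start = starts, end = starts + gene_len_bp,
                 strand = sample(c("+", "-"), n_genes, replace = TRUE),
                 protein_id = protein_id)
  centromeres <- tibble(chromosome = chroms,
                        position_bp = floor(chrom_lengths / 2))

  placed <- classify_location(loci, centromeres, chrom_lengths,
                              cfg$centromeric_radius, cfg$proximal_fraction)
  anchor <- sample.int(n_genes, cfg$n_pairs, replace = cfg$n_pairs > n_genes)
  anchor_class <- as.character(placed$location_class[anchor])
  p_pair <- cfg$p_conserve[anchor_class]
  conserved <- runif(cfg$n_pairs) < p_pair
  partner_calls <- vector("list", cfg$n_pairs)
  for (i in seq_len(cfg$n_pairs)) {
    base <- calls_list[[anchor[i]]]
    partner_calls[[i]] <- if (conserved[i]) base else mutate_mask(base, cfg)
  }
  partner_id <- paste0(protein_id[anchor], "_d", seq_len(cfg$n_pairs))
  pairs <- tibble(id_a = protein_id[anchor], id_b = partner_id)

  # sequences for genome genes + partners in one vectorised pass
  all_calls <- c(calls_list, partner_calls)
  all_ids <- c(protein_id, partner_id)
  flat <- unlist(all_calls)
  base_gc <- pmin(0.7, pmax(0.25, rnorm(length(all_calls), cfg$gc_baseline,
                                        cfg$gene_gc_sd)))
  owner <- rep.int(seq_along(all_calls), lengths(all_calls))
  coding <- sample_coding(flat, owner, base_gc, cfg, tab)
  aa_seq <- vapply(split(coding$aa, owner), paste, character(1), collapse = "")
  cds_seq <- vapply(split(coding$codon, owner), paste, character(1), collapse = "")
  names(aa_seq) <- names(cds_seq) <- NULL
  proteins <- tibble(protein_id = all_ids, sequence = aa_seq,
                     length = lengths(all_calls))
  cds <- tibble(cds_id = all_ids, sequence = paste0(cds_seq, "TAA"),
                length = nchar(cds_seq) + 3L)
  masks_all <- tibble(protein_id = all_ids, calls = all_calls)

  # domains: every genome protein gets >= 1, overlaps allowed
  nd <- 1L + rpois(n_genes, max(0, cfg$domains_per_protein_mean - 1))
  dom_gene <- rep.int(seq_len(n_genes), nd)
  dom_L <- L_aa[dom_gene]
  dom_len <- pmin(pmax(20L, round(rgamma(length(dom_gene), shape = 4,
                                         scale = cfg$domain_len_mean / 4))),
                  dom_L - 1L)
  dom_start <- floor(runif(length(dom_gene), 0, dom_L - dom_len + 1))
  domains <- tibble(protein_id = protein_id[dom_gene],
                    domain_id = paste0("d", dom_gene, ".",
                                       unlist(lapply(nd, seq_len))),
                    start = dom_start, end = dom_start + dom_len)

  truth <- list(
    window_rates = tibble(chromosome = windows$chromosome,
                          start = windows$start, end = windows$end,
                          cm = cm, recombination_rate = rate),
    gene_segments = extract_segments(masks, cfg$seg_len_min),
    beta_rec = cfg$beta_rec, lambda0 = cfg$lambda0, delta_gc = cfg$delta_gc,
    p_conserve = cfg$p_conserve,
    pair_draws = tibble(id_a = pairs$id_a, id_b = pairs$id_b,
                        location_class = anchor_class, conserved = conserved))

  structure(list(proteins = proteins, cds = cds, masks = masks_all,
                 domains = domains, loci = loci, map = map,
                 centromeres = centromeres, pairs = pairs,
                 chrom_lengths = chrom_lengths, config = cfg, truth = truth),
            class = "idr_bundle")
}

#' Write a simulated bundle to disk
#'
#' Emits the bundle in exactly the formats the package readers accept:
#' protein/CDS FASTA, a mask FASTA, GFF3 gene loci, and `#`-headed TSVs for
#' domains, genetic map, centromeres, pairs and chromosome lengths, plus the
#' ground-truth window rates as `truth_windows.tsv`.
#'
#' @param bundle An `idr_bundle` from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$proteins, p("proteins.fasta"))
  write_fasta(bundle$cds, p("cds.fasta"))
  write_disorder_masks(bundle$masks, p("masks.fasta"))
  write_domains(bundle$domains, p("domains.tsv"))
  write_gene_loci(bundle$loci, p("genes.gff3"), format = "gff3")
  write_genetic_map(bundle$map, p("map.tsv"))
  write_centromeres(bundle$centromeres, p("centromeres.tsv"))
  write_pairs(bundle$pairs, p("pairs.tsv"))
  write_hash_tsv(tibble(chromosome = names(bundle$chrom_lengths),
                        length_bp = unname(bundle$chrom_lengths)),
                 p("chrom_lengths.tsv"))
  write_hash_tsv(bundle$truth$window_rates, p("truth_windows.tsv"))
  invisible(dir)
}

#' Read an input bundle from disk
#'
#' Counterpart of [write_bundle()]; also accepts hand-assembled directories
#' following the same file layout.
#'
#' @param dir Directory holding the bundle files.
#' @return An `idr_bundle` list (without ground truth unless
#'   `truth_windows.tsv` is present).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  cl <- read_hash_tsv(p("chrom_lengths.tsv"))
  truth <- NULL
  if (file.exists(p("truth_windows.tsv"))) {
    truth <- list(window_rates = read_hash_tsv(p("truth_windows.tsv")))
  }
  structure(list(proteins = read_protein_fasta(p("proteins.fasta")),
                 cds = read_cds_fasta(p("cds.fasta")),
                 masks = read_disorder_masks(p("masks.fasta")),
                 domains = read_domains(p("domains.tsv")),
                 loci = read_gene_loci(p("genes.gff3"), format = "gff3"),
                 map = read_genetic_map(p("map.tsv")),
                 centromeres = read_centromeres(p("centromeres.tsv")),
                 pairs = read_pairs(p("pairs.tsv")),
                 chrom_lengths = setNames(cl$length_bp, cl$chromosome),
                 config = NULL, truth = truth),
            class = "idr_bundle")
}
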