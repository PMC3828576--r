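test_that("pearson correlation obeys exactness, symmetry and affine invariance", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_cor(x, x)$r, 1)
  withr::local_seed(51)
  y <- rnorm(5)
  a <- pearson_cor(x, y)
  expect_equal(pearson_cor(y, x)$r, a$r)
  expect_equal(pearson_cor(2 * x + 3, y)$r, a$r)
  expect_equal(pearson_cor(-2 * x, y)$r, -a$r)
  expect_error(pearson_cor(rep(1, 5), y), "zero variance.*x")
  expect_error(pearson_cor(x[1:2], y[1:2]), "n >= 3")
})

test_that("pearson p-value agrees with a permutation null at n = 10", {
  withr::local_seed(52)
  x <- rnorm(10)
  y <- x * 0.8 + rnorm(10, sd = 0.9)
  got <- pearson_cor(x, y)
  r_obs <- abs(got$r)
  nrep <- 1e5
  perm <- vapply(seq_len(nrep), function(i) abs(cor(x, sample(y))), numeric(1))
  p_perm <- (sum(perm >= r_obs) + 1) / (nrep + 1)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / nrep)
  expect_lt(abs(got$p - p_perm), mc_err + 0.005)
})

test_that("significance bands reproduce the star convention at the boundaries", {
  expect_equal(significance_band(c(0.0049, 0.005, 0.0099, 0.01, 0.049, 0.05, 0.5)),
               c("***", "**", "**", "*", "*", "ns", "ns"))
})

test_that("index of dispersion distinguishes random from clustered counts", {
  expect_equal(index_of_dispersion(c(5, 5, 5, 5)), 0)
  expect_error(index_of_dispersion(c(0, 0, 0)), "zero")
  expect_error(index_of_dispersion(c(-1, 2)), "non-negative")

  withr::local_seed(53)
  pois <- rpois(1e4, 4)
  expect_lt(abs(index_of_dispersion(pois) - 1), 0.05)

  # negative binomial, size k = 0.5: VMR = 1 + mu/k = 9 at mu = 4
  nb <- rnbinom(1e4, size = 0.5, mu = 4)
  vmr_nb <- index_of_dispersion(nb)
  expect_gt(vmr_nb, 1)
  expect_lt(abs(vmr_nb - 9) / 9, 0.25)
})

test_that("regression coefficients match the normal equations on a 5-point example", {
  d <- tibble::tibble(
    disordered_residue_frequency = c(0.10, 0.14, 0.20, 0.24, 0.31),
    gc_disordered_frequency = c(0.05, 0.07, 0.10, 0.12, 0.15),
    recombination_rate = c(1.0, 3.0, 2.0, 5.0, 4.0))
  fit <- fit_disorder_model(d)
  X <- cbind(1, d$gc_disordered_frequency, d$recombination_rate)
  beta <- solve(t(X) %*% X, t(X) %*% d$disordered_residue_frequency)
  expect_equal(unname(coef(fit$fit)), as.vector(beta))
  expect_gte(fit$r_squared, 0)
  expect_lte(fit$r_squared, 1)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("(Intercept)", "gc", "rec"))
  gl <- generics::glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
})

test_that("an exact linear response in G+C yields R^2 = 1 and an irrelevant rec term", {
  withr::local_seed(54)
  gc <- runif(40, 0.05, 0.3)
  d <- tibble::tibble(disordered_residue_frequency = 2 * gc + 0.01,
                      gc_disordered_frequency = gc,
                      recombination_rate = runif(40, 0, 10))
  # the deliberately exact fit makes lm warn about perfect residuals
  fit <- suppressWarnings(fit_disorder_model(d))
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$anova_p[["gc"]], 1e-10)
  expect_gt(fit$anova_p[["rec"]], 0.05)
})

test_that("regression recovers known coefficients within 2 SE in >= 95% of runs", {
  withr::local_seed(55)
  hits_gc <- hits_rec <- 0L
  for (i in 1:200) {
    n <- 500
    gc <- runif(n, 0.05, 0.3)
    rec <- rgamma(n, 2, 0.5)
    y <- 0.01 + 2.0 * gc + 0.01 * rec + rnorm(n, sd = 0.02)
    d <- tibble::tibble(disordered_residue_frequency = y,
                        gc_disordered_frequency = gc,
                        recombination_rate = rec)
    fit <- fit_disorder_model(d)
    cf <- summary(fit$fit)$coefficients
    if (abs(cf["gc", 1] - 2.0) <= 2 * cf["gc", 2]) hits_gc <- hits_gc + 1L
    if (abs(cf["rec", 1] - 0.01) <= 2 * cf["rec", 2]) hits_rec <- hits_rec + 1L
  }
  expect_gte(hits_gc / 200, 0.95)
  expect_gte(hits_rec / 200, 0.95)
})

test_that("sequential ANOVA p-values are invariant to predictor scaling", {
  withr::local_seed(56)
  d <- tibble::tibble(disordered_residue_frequency = rnorm(60, 0.2, 0.05),
                      gc_disordered_frequency = runif(60, 0.05, 0.3),
                      recombination_rate = rgamma(60, 2, 0.5))
  f1 <- fit_disorder_model(d)
  d2 <- dplyr::mutate(d, gc_disordered_frequency = gc_disordered_frequency * 100,
                      recombination_rate = recombination_rate / 7)
  f2 <- fit_disorder_model(d2)
  expect_equal(f1$anova_p, f2$anova_p)
  expect_equal(f1$r_squared, f2$r_squared)
})

test_that("rank-deficient and tiny designs are refused", {
  d <- tibble::tibble(disordered_residue_frequency = c(0.1, 0.2, 0.3, 0.4),
                      gc_disordered_frequency = c(0.1, 0.2, 0.3, 0.4),
                      recombination_rate = c(0.2, 0.4, 0.6, 0.8))
  expect_error(fit_disorder_model(d), "rank")
  expect_error(fit_disorder_model(d[1:3, ]), "more than 3")
})

test_that("hypergeometric enrichment equals the combinatorial and Fisher oracles", {
  population <- sprintf("m%03d", 1:20)
  study <- population[1:5]
  ann <- tibble::tibble(id = population,
                        term = rep(c("T1", "T2"), c(5, 15)))
  # T1 annotates 5/20 of the population and 4/5 of the study
  ann$term[1:4] <- "T1"
  ann$term[5] <- "T2"
  ann$term[6] <- "T1"
  res <- term_enrichment(study, population, ann)
  t1 <- res[res$term == "T1", ]
  # closed-form hypergeometric upper tail
  p_manual <- sum(dhyper(4:5, 5, 15, 5))
  expect_equal(t1$p_raw, p_manual)
  # one-tailed Fisher on the printed 2x2
  fisher_p <- fisher.test(matrix(c(4, 1, 1, 14), 2), alternative = "greater")$p.value
  expect_equal(t1$p_raw, fisher_p)
  # Bonferroni never drops below raw and caps at 1
  expect_true(all(res$p_corrected >= res$p_raw))
  expect_true(all(res$p_corrected <= 1))
})

test_that("enrichment degenerates correctly when study equals the population", {
  population <- sprintf("m%03d", 1:30)
  ann <- tibble::tibble(id = population, term = rep(c("A", "B", "C"), each = 10))
  res <- term_enrichment(population, population, ann)
  expect_equal(res$p_raw, rep(1, 3))
  expect_error(term_enrichment(character(0), population, ann), "empty")
  expect_error(term_enrichment("zzz", population, ann), "subset")
  # BH correction selectable
  res_bh <- term_enrichment(population[1:10], population, ann, correction = "bh")
  expect_true(all(res_bh$p_corrected >= res_bh$p_raw - 1e-12))
})
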