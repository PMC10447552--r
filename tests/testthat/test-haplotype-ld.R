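test_that("LD statistics match the closed-form definitions", {
  perfect <- ld_stats(c(0.5, 0, 0, 0.5))
  expect_equal(perfect$D, 0.25)
  expect_equal(perfect$D_prime, 1)
  expect_equal(perfect$r2, 1)

  # independence: frequencies are products of the marginals
  indep <- ld_stats(c(0.3 * 0.6, 0.3 * 0.4, 0.7 * 0.6, 0.7 * 0.4))
  expect_equal(indep$D, 0, tolerance = 1e-12)
  expect_equal(indep$r2, 0, tolerance = 1e-12)

  mid <- ld_stats(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(mid$D, 0.15)
  expect_equal(mid$D_prime, 0.6)
  expect_equal(mid$r2, 0.36)

  expect_error(ld_stats(c(0.5, 0.5, 0, 0)), "fixed allele")
})

test_that("r2 never exceeds D-prime squared on random frequency draws", {
  set.seed(101)
  for (i in 1:1000) {
    f <- rexp(4); f <- f / sum(f)
    s <- tryCatch(ld_stats(f), error = function(e) NULL)
    if (is.null(s)) next
    expect_lte(s$r2, s$D_prime^2 + 1e-9)
  }
})

test_that("the genotype grid has exactly the nine categories", {
  grid <- enumerate_genotype_combinations()
  expect_equal(nrow(grid), 9L)
  expect_equal(anyDuplicated(grid$label), 0L)
  expect_true(any(grid$snp == "T/T" & grid$mnlp == "S/L"))
  expect_setequal(unique(grid$snp), c("T/T", "T/C", "C/C"))
  expect_setequal(unique(grid$mnlp), c("S/S", "S/L", "L/L"))
})

test_that("recombinant classification counts non-coupling haplotypes", {
  expect_equal(classify_recombinant("T/T", "S/S")$min_recombinant_haplotypes, 0L)
  expect_false(classify_recombinant("T/T", "S/S")$is_recombinant)
  expect_equal(classify_recombinant("T/T", "S/L")$min_recombinant_haplotypes, 1L)
  expect_true(classify_recombinant("T/T", "S/L")$is_recombinant)
  expect_equal(classify_recombinant("T/T", "L/L")$min_recombinant_haplotypes, 2L)
  expect_equal(classify_recombinant("T/C", "S/L")$min_recombinant_haplotypes, 0L)

  # invariance under swapping which locus comes first
  for (snp in c("T/T", "T/C", "C/C")) for (mnlp in c("S/S", "S/L", "L/L")) {
    a <- classify_recombinant(snp, mnlp, coupling = c("T-S", "C-L"))
    b <- classify_recombinant(mnlp, snp, coupling = c("S-T", "L-C"))
    expect_equal(a$min_recombinant_haplotypes, b$min_recombinant_haplotypes)
  }
})

test_that("EM equals direct counting when no double heterozygotes exist", {
  coh <- data.frame(
    snp_dosage = c(rep(2L, 6), rep(0L, 8), rep(1L, 4)),
    mnlp_dosage = c(rep(0L, 6), rep(2L, 8), rep(2L, 4)))
  em <- em_haplotype_freqs(coh)
  # direct counts: 12 T-S, 8+8 C-L + 4 C-L, 4 T-L
  n2 <- 2 * nrow(coh)
  expect_equal(unname(em$freqs),
               c(12, 4, 0, 16 + 4) / n2, tolerance = 1e-9)
})

test_that("EM resolves the balanced double-heterozygote cohort to full coupling", {
  coh <- data.frame(
    snp_dosage = c(rep(2L, 25), rep(0L, 25), rep(1L, 50)),
    mnlp_dosage = c(rep(0L, 25), rep(2L, 25), rep(1L, 50)))
  em <- em_haplotype_freqs(coh)
  expect_equal(unname(em$freqs[c("TS", "CL")]), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(ld_stats(em)$D_prime, 1, tolerance = 1e-6)
})

test_that("EM matches the grid-search oracle and recovers the truth", {
  for (seed in c(1, 2, 3)) {
    coh <- gen_two_locus_cohort(fx_model, 200, seed = seed)
    em <- em_haplotype_freqs(coh)
    oracle <- oracle_grid_haplotype_freqs(coh$snp_dosage, coh$mnlp_dosage)
    expect_lt(max(abs(em$freqs - oracle)), 1e-3)
  }

  # parameter recovery within 3 binomial standard errors at n = 5000
  coh <- gen_two_locus_cohort(fx_model, 5000, seed = 9)
  em <- em_haplotype_freqs(coh)
  se <- sqrt(fx_model$hap_freqs * (1 - fx_model$hap_freqs) / (2 * 5000))
  expect_true(all(abs(em$freqs - fx_model$hap_freqs) < 3 * se + 1e-12))

  # phased counting bypasses the EM when requested
  emp <- em_haplotype_freqs(coh, use_phase = TRUE)
  direct <- table(factor(c(coh$hap1, coh$hap2),
                         levels = c("T-S", "T-L", "C-S", "C-L"))) / 10000
  expect_equal(unname(emp$freqs), as.numeric(direct))

  expect_error(em_haplotype_freqs(data.frame(snp_dosage = c(1, 1),
                                             mnlp_dosage = c(0, 1))),
               "monomorphic")
})

test_that("EM log-likelihood is non-decreasing over iterations", {
  coh <- gen_two_locus_cohort(fx_model, 150, seed = 77)
  lls <- vapply(1:8, function(k)
    em_haplotype_freqs(coh, tol = 0, max_iter = k)$loglik, numeric(1))
  expect_true(all(diff(lls) > -1e-9))
})

test_that("genotype-trait association reports Pearson r and group means", {
  r1 <- genotype_trait_association(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2))
  expect_equal(r1$r, 1)
  expect_lte(r1$p_value, 1e-10)
  expect_equal(unname(r1$group_means), c(0, 1, 2))

  # null calibration under permutation
  set.seed(55)
  dosage <- sample(0:2, 1000, replace = TRUE)
  trait <- dosage + rnorm(1000, 0, 0.5)
  hits <- sum(vapply(1:200, function(i) {
    abs(genotype_trait_association(sample(trait), dosage)$r) < 0.1
  }, logical(1)))
  expect_gte(hits, 190)

  expect_error(genotype_trait_association(rep(1, 5), c(0, 1, 2, 1, 0)),
               "degenerate")
})

test_that("recombinants separate the MNLP effect from the index SNP", {
  m <- population_model(hap_freqs = c(0.427, 0.073, 0.073, 0.427),
                        eqtl_beta = 1, expr_sd = 0.1)
  wins <- 0L
  n_seeds <- 40L
  for (seed in seq_len(n_seeds)) {
    coh <- gen_two_locus_cohort(m, 500, seed = 500 + seed)
    cmp <- compare_eqtl_variants(coh$trait, coh$snp_dosage, coh$mnlp_dosage)
    if (abs(cmp$partial_r_mnlp) > abs(cmp$partial_r_snp)) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_seeds))

  # no signal: both partial correlations near zero
  coh0 <- gen_two_locus_cohort(population_model(eqtl_beta = 0), 500, seed = 13)
  cmp0 <- compare_eqtl_variants(rnorm(500), coh0$snp_dosage, coh0$mnlp_dosage)
  expect_lt(abs(cmp0$partial_r_snp), 0.15)
  expect_lt(abs(cmp0$partial_r_mnlp), 0.15)

  # recombinant T/T carriers of the long allele sit above T/T short-only
  m2 <- population_model(hap_freqs = c(0.4, 0.1, 0.1, 0.4),
                         eqtl_beta = 1, expr_sd = 0.5)
  coh2 <- gen_two_locus_cohort(m2, 2000, seed = 14)
  cmp2 <- compare_eqtl_variants(coh2$trait, coh2$snp_dosage, coh2$mnlp_dosage)
  expect_gt(cmp2$grid_means["2", "1"], cmp2$grid_means["2", "0"])
})
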