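test_that("two-locus cohort respects haplotype structure and determinism", {
  # only coupling haplotypes: T count must mirror S count
  m <- population_model(hap_freqs = c(0.5, 0, 0, 0.5))
  coh <- gen_two_locus_cohort(m, 4, seed = 11)
  expect_equal(coh$snp_dosage, 2L - coh$mnlp_dosage)

  # no effect, no noise: all traits exactly zero
  m0 <- population_model(eqtl_beta = 0, expr_sd = 0)
  coh0 <- gen_two_locus_cohort(m0, 10, seed = 12)
  expect_equal(coh0$trait, rep(0, 10))

  expect_identical(gen_two_locus_cohort(fx_model, 50, seed = 3),
                   gen_two_locus_cohort(fx_model, 50, seed = 3))
  expect_error(population_model(hap_freqs = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("empirical haplotype frequencies converge to the model", {
  m <- population_model(hap_freqs = c(0.4, 0.1, 0.1, 0.4))
  coh <- gen_two_locus_cohort(m, 20000, seed = 21)
  emp <- table(factor(c(coh$hap1, coh$hap2),
                      levels = c("T-S", "T-L", "C-S", "C-L"))) / 40000
  expect_true(all(abs(as.numeric(emp) - c(0.4, 0.1, 0.1, 0.4)) < 0.01))
})

test_that("amplicon reads follow the genotype and are seed-deterministic", {
  ctx_l <- paste0(fx_spec$flank_left, fx_spec$seq_l, fx_spec$flank_right)
  rl <- gen_amplicon_reads(fx_spec, "L/L", 50, error_rate = 0, seed = 5)
  expect_true(all(rl$seq == ctx_l))

  het <- gen_amplicon_reads(fx_spec, "S/L", 10000, error_rate = 0, seed = 6)
  frac_s <- mean(attr(het, "origin") == "S")
  expect_gt(frac_s, 0.47)
  expect_lt(frac_s, 0.53)

  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(gen_amplicon_reads(fx_spec, "S/L", 300, 0.01, seed = 7), f1)
  write_fastq(gen_amplicon_reads(fx_spec, "S/L", 300, 0.01, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_identical(nrow(gen_amplicon_reads(fx_spec, "S/S", 0, seed = 1)), 0L)
  expect_error(gen_amplicon_reads(fx_spec, "S/L", 10, error_rate = 0.5), "error_rate")
})

test_that("depth profiles scale the allele segment with dosage", {
  dp <- gen_depth_profiles(fx_spec, c("S/S", "S/L", "L/L"), mean_depth = 80,
                           noise_cv = 0, seed = 2)
  li <- (dp$l_interval[1] + 1):dp$l_interval[2]
  flank <- setdiff(seq_len(ncol(dp$l_depth)), li)
  expect_equal(unname(dp$l_depth[1, li]), rep(0, length(li)))       # S/S
  expect_equal(unname(dp$l_depth[2, li]), rep(40, length(li)))      # S/L
  expect_equal(unname(dp$l_depth[3, li]), rep(80, length(li)))      # L/L
  expect_equal(unname(dp$l_depth[1, flank]), rep(80, length(flank)))

  # multiplicative noise: flank sample mean near the target depth
  dpn <- gen_depth_profiles(fx_spec, rep("S/L", 20), mean_depth = 100,
                            noise_cv = 0.1, seed = 3)
  flank_vals <- dpn$l_depth[, flank]
  expect_gt(length(flank_vals), 1000)
  expect_lt(abs(mean(flank_vals) - 100), 3)
})

test_that("allele-specific counts have binomial and beta-binomial variance", {
  peaks <- synth_peaks(1, 0)
  m0 <- population_model(rho_normal = 0)
  tab0 <- gen_ase_counts(m0, 500, peaks, sites_per_peak = 20,
                         depth_law = function(n) rep(50L, n), seed = 31,
                         conditions = "normal")
  expect_equal(nrow(tab0), 10000L)
  v <- var(tab0$hapA_count / 50)
  expect_lt(abs(v - 0.25 / 50), 0.15 * 0.25 / 50)

  m2 <- population_model(rho_normal = 0.2)
  tab2 <- gen_ase_counts(m2, 500, peaks, sites_per_peak = 20,
                         depth_law = function(n) rep(50L, n), seed = 32,
                         conditions = "normal")
  target <- 50 * 0.25 * (1 + 49 * 0.2)
  expect_lt(abs(var(tab2$hapA_count) - target), 0.10 * target)

  # allelic ratio of 1 is outside the open interval
  expect_error(population_model(ase_p = 1), "ase_p")
})

test_that("cv panel: perfect LD without recombination, calibrated null Z", {
  m <- population_model(n_snps = 40, founder_count = 2, switch_rate = 0)
  p <- suppressMessages(gen_cv_panel(m, 200, seed = 41))
  expect_true(all(abs(abs(p$r_cv) - 1) < 1e-12))

  m0 <- population_model(n_snps = 1000, gwas_beta = 0)
  p0 <- suppressMessages(gen_cv_panel(m0, 200, seed = 42))
  frac <- mean(abs(p0$gwas_z) > 1.96)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)

  expect_identical(suppressMessages(gen_cv_panel(fx_model, 100, seed = 43)),
                   suppressMessages(gen_cv_panel(fx_model, 100, seed = 43)))
})

test_that("generated LD matrix is positive semidefinite after ridge fix", {
  p <- suppressMessages(gen_cv_panel(fx_model, 150, seed = 44))
  ev <- eigen(p$ld + diag(1e-6, nrow(p$ld)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_equal(unname(diag(p$ld)), rep(1, nrow(p$ld)))
})

test_that("sampled-mode GWAS Z-scores carry the causal signal", {
  m <- population_model(n_snps = 30, gwas_beta = 0.08)
  p <- suppressMessages(gen_cv_panel(m, 150, seed = 45, mode = "sampled"))
  expect_identical(p$mode, "sampled")
  # strongest tags should show strong association
  expect_gt(max(abs(p$gwas_z)), 3)
})
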