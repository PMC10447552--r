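test_that("beta-binomial log-likelihood is symmetric, normalized, binomial at rho 0", {
  expect_equal(betabinom_loglik(7, 20, 0.5, 0.1),
               betabinom_loglik(13, 20, 0.5, 0.1))
  expect_equal(betabinom_loglik(3, 10, 0.5, 0),
               dbinom(3, 10, 0.5, log = TRUE))
  expect_lt(abs(sum(exp(betabinom_loglik(0:25, 25, 0.3, 0.1))) - 1), 1e-10)
  expect_error(betabinom_loglik(3, 10, 0.5, 1), "rho")
  expect_error(betabinom_loglik(11, 10, 0.5, 0.1), "counts")
})

test_that("beta-binomial draws match the closed-form mean and variance", {
  set.seed(8)
  x <- rbetabinom(20000, 60, 0.3, 0.08)
  expect_lt(abs(mean(x) - 60 * 0.3), 0.2)
  target <- 60 * 0.3 * 0.7 * (1 + 59 * 0.08)
  expect_lt(abs(var(x) - target), 0.1 * target)
})

test_that("overdispersion estimation recovers the truth and flags edge cases", {
  # perfectly balanced large counts carry no overdispersion signal
  bal <- estimate_overdispersion(rep(50, 20), rep(100, 20))
  expect_equal(bal$rho_hat, 0)

  set.seed(91)
  k <- rbetabinom(500, 50, 0.5, 0.05)
  est <- estimate_overdispersion(k, rep(50, 500))
  expect_gte(est$rho_hat, 0.03)
  expect_lte(est$rho_hat, 0.07)

  # bimodal all-or-nothing counts push rho to the upper bound
  bim <- estimate_overdispersion(c(rep(0, 10), rep(50, 10)), rep(50, 20))
  expect_gte(bim$rho_hat, 0.9)

  single <- estimate_overdispersion(5, 10)
  expect_equal(single$rho_hat, 0)
  expect_equal(single$note, "unidentifiable")
})

test_that("peak-level merging sums haplotype counts per individual", {
  tab <- data.frame(individual = "i1", condition = "normal",
                    peak_id = "p1", site_id = c("s1", "s2"),
                    site_position = c(10, 20),
                    hapA_count = c(3, 5), hapB_count = c(7, 5))
  m <- merge_peak_counts(tab)
  expect_equal(m$K, 8)
  expect_equal(m$N, 20)

  single <- merge_peak_counts(tab[1, ])
  expect_equal(single$K, 3)
  expect_equal(single$N, 10)
})

test_that("variant-to-peak assignment is inclusive at the window boundary", {
  peaks <- data.frame(peak_id = "p1", start = 0L, end = 2000L)  # center 1000
  v <- function(pos, het) data.frame(variant_id = "v1", pos = pos,
                                     het_individuals = het,
                                     stringsAsFactors = FALSE)
  expect_equal(nrow(assign_variants_to_peaks(v(101000, "i1"), peaks)), 1L)
  expect_equal(nrow(assign_variants_to_peaks(v(101001, "i1"), peaks)), 0L)
  expect_equal(nrow(assign_variants_to_peaks(v(1000, ""), peaks)), 0L)
})

test_that("combined imbalance test matches the binomial LRT oracle", {
  bal <- test_imbalance(rep(50, 5), rep(100, 5))
  expect_equal(bal$lrt_stat, 0, tolerance = 1e-6)
  expect_equal(bal$p_value, 1, tolerance = 1e-4)

  strong <- test_imbalance(rep(90, 10), rep(100, 10))
  expect_lt(strong$p_value, 1e-10)

  one <- test_imbalance(60, 100)
  expect_equal(one$lrt_stat, oracle_binom_lrt(60, 100), tolerance = 1e-4)
  expect_equal(one$p_hat, 0.6, tolerance = 1e-3)

  expect_error(test_imbalance(numeric(), numeric()), "no individuals")
})

test_that("exact enumeration p-value is used and valid at tiny depth", {
  r <- test_imbalance(c(5, 4), c(6, 5), 0)
  expect_identical(r$method, "exact")
  expect_gte(r$p_value, 0)
  expect_lte(r$p_value, 1)
  # exact p at least as large as the probability of the observed config
  r2 <- test_imbalance(c(3, 2), c(6, 4), 0)
  expect_equal(r2$p_value, 1, tolerance = 1e-9)  # perfectly balanced
})

test_that("differential test separates conditions and is label-symmetric", {
  same <- test_differential(c(30, 28), c(50, 50), c(30, 28), c(50, 50))
  expect_lt(same$lrt_stat, 1e-6)
  expect_equal(same$p_value, 1, tolerance = 1e-3)

  set.seed(17)
  ps <- vapply(1:50, function(i) {
    kt <- rbetabinom(10, 200, 0.8, 0.01)
    kn <- rbetabinom(10, 200, 0.5, 0.01)
    test_differential(kt, rep(200, 10), kn, rep(200, 10), 0.01, 0.01)$p_value
  }, numeric(1))
  expect_lt(median(ps), 1e-6)

  a <- test_differential(c(40, 45), c(60, 70), c(20, 25), c(60, 70), 0.02, 0.01)
  b <- test_differential(c(20, 25), c(60, 70), c(40, 45), c(60, 70), 0.01, 0.02)
  expect_equal(a$lrt_stat, b$lrt_stat, tolerance = 1e-8)

  expect_error(test_differential(numeric(), numeric(), c(1), c(2)), "both conditions")
})

test_that("allele swap leaves all p-values unchanged", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(20:120, 8, replace = TRUE)
    k <- rbetabinom(8, n, 0.7, 0.01)
    a <- test_imbalance(k, n, 0.01)
    b <- test_imbalance(n - k, n, 0.01)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-6)
    d1 <- test_differential(k[1:4], n[1:4], k[5:8], n[5:8], 0.01, 0.01)
    d2 <- test_differential(n[1:4] - k[1:4], n[1:4], n[5:8] - k[5:8], n[5:8],
                            0.01, 0.01)
    expect_equal(d1$p_value, d2$p_value, tolerance = 1e-6)
  }
})

test_that("BH step-up control matches the hand-computed rule", {
  adj <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.10)
  expect_true(all(adj$significant))          # p_(i) <= i * 0.10 / 4 for all i
  expect_equal(adj$q_value, p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"))

  expect_true(fdr_bh(0.05, q = 0.10)$significant)
  expect_equal(nrow(fdr_bh(numeric())), 0L)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("peaks are flagged per category from any significant variant", {
  res <- data.frame(
    peak_id = c(rep("p1", 5), rep("p2", 3)),
    category = "normal",
    q_value = c(0.04, 0.5, 0.6, 0.9, 0.2, 0.5, 0.7, 0.2))
  fl <- call_imbalanced_peaks(res, q = 0.10)
  expect_true(fl$flagged[fl$peak_id == "p1"])
  expect_false(fl$flagged[fl$peak_id == "p2"])

  # categories are independent
  res2 <- rbind(res, data.frame(peak_id = "p2", category = "tumor",
                                q_value = 0.01))
  fl2 <- call_imbalanced_peaks(res2, q = 0.10)
  expect_false(fl2$flagged[fl2$peak_id == "p2" & fl2$category == "normal"])
  expect_true(fl2$flagged[fl2$peak_id == "p2" & fl2$category == "tumor"])
})

test_that("full analysis flags a planted imbalanced peak and not the nulls", {
  m <- population_model(ase_p = 0.9, rho_normal = 5e-4, rho_tumor = 2.7e-3)
  tab <- gen_ase_counts(m, 10, synth_peaks(5, 1), sites_per_peak = 2,
                        depth_law = function(n) rep(50L, n), seed = 66)
  ana <- run_ase_analysis(tab)
  flagged <- ana$peak_flags[ana$peak_flags$flagged, ]
  expect_true("peak_01" %in% flagged$peak_id)
  expect_false(any(flagged$peak_id != "peak_01" &
                   flagged$category != "differential"))
  expect_true(all(ana$results$q_value >= ana$results$p_value - 1e-12))
})
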