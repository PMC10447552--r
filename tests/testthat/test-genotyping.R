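test_that("allele references differ only in the allele interval", {
  refs <- fx_refs
  expect_equal(nchar(refs$l_ref) - nchar(refs$s_ref), 26L)
  expect_equal(diff(refs$s_interval), 21L)
  expect_equal(diff(refs$l_interval), 47L)
  fl <- refs$s_interval[1]
  expect_identical(substr(refs$s_ref, 1, fl), substr(refs$l_ref, 1, fl))
  expect_identical(substr(refs$s_ref, refs$s_interval[2] + 1, nchar(refs$s_ref)),
                   substr(refs$l_ref, refs$l_interval[2] + 1, nchar(refs$l_ref)))
  tight <- mnlp_allele_spec(flank_left = strrep("ACGTT", 6),
                            flank_right = strrep("TGCAA", 6))
  expect_error(build_allele_references(tight, min_flank = 35), "anchor")
})

test_that("read classification assigns, abstains and rejects correctly", {
  # error-free homozygous long reads: no short or ambiguous assignments
  rl <- gen_amplicon_reads(fx_spec, "L/L", 100, error_rate = 0, seed = 1)
  cls <- classify_amplicon_reads(rl, fx_refs)
  expect_equal(cls$n_s, 0L)
  expect_equal(cls$n_ambiguous, 0L)
  expect_equal(cls$n_l, 100L)
  expect_equal(sum(cls$n_s, cls$n_l, cls$n_ambiguous, cls$n_unmatched),
               cls$n_total)
  expect_equal(sum(cls$read_types), cls$n_s + cls$n_l)

  # one substitution in an s_ref copy still scores 98 >= 0.9 * 100
  mut <- fx_refs$s_ref
  substr(mut, 50, 50) <- if (substr(mut, 50, 50) == "A") "C" else "A"
  one <- classify_amplicon_reads(data.frame(seq = mut), fx_refs,
                                 max_mismatch_frac = 0.05)
  expect_equal(one$n_s, 1L)

  # flank-only read matches both references equally: ambiguous
  fl <- classify_amplicon_reads(data.frame(seq = fx_spec$flank_left), fx_refs)
  expect_equal(fl$n_ambiguous, 1L)

  # non-ACGTN characters are counted unmatched with a warning
  expect_warning(
    bad <- classify_amplicon_reads(data.frame(seq = "ACGTXACGT"), fx_refs),
    "non-ACGTN")
  expect_equal(bad$n_unmatched, 1L)
})

test_that("classification is symmetric under swapping the S and L labels", {
  reads <- gen_amplicon_reads(fx_spec, "S/L", 400, error_rate = 0.01, seed = 2)
  cls <- classify_amplicon_reads(reads, fx_refs)
  swapped_spec <- mnlp_allele_spec(seq_s = fx_spec$seq_l, seq_l = fx_spec$seq_s)
  cls_sw <- classify_amplicon_reads(reads, build_allele_references(swapped_spec))
  expect_equal(cls$n_s, cls_sw$n_l)
  expect_equal(cls$n_l, cls_sw$n_s)
  expect_equal(cls$n_ambiguous, cls_sw$n_ambiguous)
})

test_that("read-based genotype calls follow the L-fraction band", {
  expect_equal(call_genotype_from_reads(make_classification(0, 1000))$genotype, "L/L")
  expect_equal(call_genotype_from_reads(make_classification(0, 1000))$l_fraction, 1.0)
  expect_equal(call_genotype_from_reads(make_classification(520, 480))$genotype, "S/L")
  nc <- call_genotype_from_reads(make_classification(30, 10), min_reads = 50)
  expect_equal(nc$genotype, "no-call")
  expect_match(nc$qc_reason, "insufficient")
  zero <- call_genotype_from_reads(make_classification(0, 0))
  expect_equal(zero$genotype, "no-call")
})

test_that("pooled allele frequency uses the Wilson interval", {
  all_l <- estimate_pool_allele_freq(make_classification(0, 100))
  expect_equal(all_l$freq_l, 1.0)
  expect_equal(all_l$ci[2], 1.0)

  half <- estimate_pool_allele_freq(make_classification(50, 50))
  expect_equal(half$freq_l, 0.5)
  expect_equal(half$ci[1] - 0.5, -(half$ci[2] - 0.5))

  q <- estimate_pool_allele_freq(make_classification(75, 25))
  expect_equal(q$freq_l, 0.25)
  expect_equal(q$ci, oracle_wilson(25, 100), tolerance = 1e-10)

  expect_error(estimate_pool_allele_freq(make_classification(0, 0)), "no classified")
})

test_that("coverage-based genotype calls follow the relative-depth bands", {
  dp <- gen_depth_profiles(fx_spec, c("L/L", "S/L", "S/S"), mean_depth = 100,
                           noise_cv = 0, seed = 1)
  calls <- call_genotypes_from_coverage(dp, fx_refs)
  expect_equal(calls$genotype, c("L/L", "S/L", "S/S"))
  expect_equal(calls$rel_depth_l, c(1, 0.5, 0))

  shallow <- call_genotype_from_coverage(
    list(l_depth = rep(2, nchar(fx_refs$l_ref))), fx_refs, min_depth = 10)
  expect_equal(shallow$genotype, "no-call")

  bad_refs <- fx_refs
  bad_refs$l_interval <- c(40, 40)
  expect_error(call_genotype_from_coverage(
    list(l_depth = rep(50, nchar(fx_refs$l_ref))), bad_refs), "empty")
})

test_that("knock-in verification passes intact clones and fails mutants", {
  clean <- gen_amplicon_reads(fx_spec, "L/L", 300, error_rate = 0, seed = 4)
  rep1 <- verify_knockin(clean, fx_refs)
  expect_true(rep1$pass)
  expect_equal(rep1$border_fraction, 1.0)

  # mutate the left border in every read: verification must fail
  iv <- fx_refs$l_interval
  mutated <- vapply(clean$seq, function(s) {
    substr(s, iv[1] - 3, iv[1]) <- "AAAA"; s
  }, character(1), USE.NAMES = FALSE)
  rep2 <- verify_knockin(data.frame(seq = mutated, stringsAsFactors = FALSE),
                         fx_refs)
  expect_false(rep2$pass)

  # sporadic sequencing errors do not fail the clone and leave no
  # recurrent-variant calls
  noisy <- gen_amplicon_reads(fx_spec, "L/L", 400, error_rate = 0.02, seed = 5)
  rep3 <- verify_knockin(noisy, fx_refs)
  expect_true(rep3$pass)
  expect_equal(nrow(rep3$recurrent_variants), 0L)

  # no long-allele reads at all
  ss <- gen_amplicon_reads(fx_spec, "S/S", 100, error_rate = 0, seed = 6)
  rep4 <- verify_knockin(ss, fx_refs)
  expect_false(rep4$pass)
  expect_match(rep4$reason, "no L")
})

test_that("coverage-based discovery finds planted dips and filters noise", {
  set.seed(71)
  n <- 40
  dos <- sample(0:2, n, replace = TRUE)
  flat <- matrix(1 + rnorm(n * 15, 0, 0.05), n, 15)
  expect_equal(nrow(discover_complex_variants(flat, dos)), 0L)

  planted <- flat
  planted[, 7] <- 1 - dos / 2 + rnorm(n, 0, 0.04)
  res <- discover_complex_variants(planted, dos)
  expect_equal(nrow(res), 1L)
  expect_equal(res$r2, 1)
  expect_equal(res$start, 6 * 500)

  # permuting the dip across samples destroys the correlation
  permuted <- flat
  permuted[, 7] <- (1 - dos / 2)[sample(n)] + rnorm(n, 0, 0.04)
  res_p <- discover_complex_variants(permuted, dos, min_r2 = 0.5)
  expect_equal(nrow(res_p), 0L)

  expect_error(discover_complex_variants(planted, rep(1, n)), "monomorphic")
  expect_error(discover_complex_variants(planted[1:5, ], dos[1:5]), "10 samples")
})

test_that("adjacent candidate windows merge into one interval", {
  set.seed(72)
  n <- 30
  dos <- sample(0:2, n, replace = TRUE)
  depth <- matrix(1 + rnorm(n * 10, 0, 0.03), n, 10)
  depth[, 4] <- 1 - dos / 2 + rnorm(n, 0, 0.03)
  depth[, 5] <- 1 - dos / 2 + rnorm(n, 0, 0.03)
  res <- discover_complex_variants(depth, dos)
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_windows, 2L)
  expect_equal(res$end - res$start, 1000L)
})
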