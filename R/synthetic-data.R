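# Seeded generators for every input the pipeline consumes. All generators
# restore the caller's RNG state and are byte-deterministic per seed.

hap_labels <- c("T-S", "T-L", "C-S", "C-L")

#' Simulate a two-locus cohort (index SNP x MNLP) with an expression trait
#'
#' Draws `2n` haplotypes i.i.d. from the model's four haplotype frequencies,
#' pairs them into diploid samples, and generates an expression value with an
#' additive effect of MNLP long-allele dosage plus Gaussian noise. Phase is
#' retained, so the unphased EM estimator can be validated against truth.
#'
#' @param model a [population_model()].
#' @param n number of diploid samples (>= 1).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A data.frame with columns `sample_id`, `hap1`, `hap2` (haplotype
#'   labels such as `"T-S"`), `snp_dosage` (count of the T risk allele),
#'   `mnlp_dosage` (count of the L allele) and `trait`.
#' @examples
#' coh <- gen_two_locus_cohort(population_model(), n = 121, seed = 1)
#' table(coh$snp_dosage, coh$mnlp_dosage)
#' @export
gen_two_locus_cohort <- function(model, n, seed) {
  stopifnot(inherits(model, "population_model"))
  if (n < 1L) stop("'n' must be >= 1")
  with_seed(seed, {
    haps <- sample.int(4L, 2L * n, replace = TRUE, prob = model$hap_freqs)
    h1 <- haps[seq_len(n)]
    h2 <- haps[n + seq_len(n)]
    snp_dos <- (h1 <= 2L) + (h2 <= 2L)              # T on haplotypes 1,2
    mnlp_dos <- (h1 %% 2L == 0L) + (h2 %% 2L == 0L) # L on haplotypes 2,4
    trait <- model$eqtl_beta * mnlp_dos + stats::rnorm(n, 0, model$expr_sd)
    data.frame(sample_id = sprintf("S%04d", seq_len(n)),
               hap1 = hap_labels[h1], hap2 = hap_labels[h2],
               snp_dosage = as.integer(snp_dos),
               mnlp_dosage = as.integer(mnlp_dos),
               trait = trait, stringsAsFactors = FALSE)
  })
}

normalize_genotype <- function(genotype) {
  g <- toupper(gsub("[^SL]", "", genotype))
  g <- paste(sort(strsplit(g, "")[[1]], decreasing = TRUE), collapse = "/")
  if (!g %in% c("S/S", "S/L", "L/L"))
    stop(sprintf("invalid MNLP genotype '%s' (expected S/S, S/L or L/L)", genotype))
  g
}

mutate_reads <- function(seqs, error_rate) {
  if (error_rate == 0 || length(seqs) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < error_rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate amplicon sequencing reads over the MNLP
#'
#' Reads are drawn from the two allelic amplicon contexts according to the
#' sample genotype (50/50 in expectation for heterozygotes), truncated to
#' `read_len` from the amplicon start (full amplicons when `read_len` covers
#' them), with independent per-base substitution errors.
#'
#' @param spec an [mnlp_allele_spec()].
#' @param genotype `"S/S"`, `"S/L"` or `"L/L"`.
#' @param n_reads number of reads (0 gives an empty read set).
#' @param error_rate per-base substitution probability in `[0, 0.2]`.
#' @param read_len read length; `NULL` (default) means full-amplicon reads.
#' @param seed integer seed.
#' @return A data.frame of class `fastq_reads` with columns `id`, `seq`,
#'   `qual`, plus attribute `origin` (true allele per read).
#' @export
gen_amplicon_reads <- function(spec, genotype, n_reads, error_rate = 0.001,
                               read_len = NULL, seed = 1) {
  stopifnot(inherits(spec, "mnlp_allele_spec"))
  if (error_rate < 0 || error_rate > 0.2) stop("'error_rate' must lie in [0, 0.2]")
  if (n_reads < 0) stop("'n_reads' must be >= 0")
  g <- normalize_genotype(genotype)
  ctx <- c(S = paste0(spec$flank_left, spec$seq_s, spec$flank_right),
           L = paste0(spec$flank_left, spec$seq_l, spec$flank_right))
  if (!is.null(read_len) &&
      read_len < nchar(spec$flank_left) + max(nchar(spec$seq_s), nchar(spec$seq_l)) + 1L)
    stop("'read_len' must span the left flank plus the longest allele (or NULL for full amplicons)")
  alleles <- strsplit(g, "/")[[1]]
  with_seed(seed, {
    origin <- if (alleles[1] == alleles[2]) rep(alleles[1], n_reads)
              else c("S", "L")[stats::rbinom(n_reads, 1L, 0.5) + 1L]
    seqs <- unname(ctx[origin])
    if (!is.null(read_len)) seqs <- substr(seqs, 1L, read_len)
    seqs <- mutate_reads(seqs, error_rate)
    out <- data.frame(id = sprintf("read_%06d", seq_len(n_reads)),
                      seq = as.character(seqs),
                      qual = strrep("I", nchar(seqs)),
                      stringsAsFactors = FALSE)
    if (n_reads == 0L)
      out <- data.frame(id = character(), seq = character(), qual = character(),
                        stringsAsFactors = FALSE)
    attr(out, "origin") <- as.character(origin)
    class(out) <- c("fastq_reads", "data.frame")
    out
  })
}

#' Simulate per-base sequencing depth over the allele-specific references
#'
#' For each sample, depth over the allele-specific segment of each reference
#' scales with that allele's dosage/2 while flank depth is genotype
#' independent; multiplicative gamma noise with coefficient of variation
#' `noise_cv` is applied per base (no noise when `noise_cv = 0`).
#'
#' @param spec an [mnlp_allele_spec()].
#' @param genotypes character vector of MNLP genotypes, one per sample.
#' @param mean_depth expected flank depth (> 0).
#' @param noise_cv coefficient of variation of multiplicative depth noise.
#' @param seed integer seed.
#' @return A `depth_profiles` list: matrices `s_depth`, `l_depth`
#'   (samples x reference positions), the 0-based half-open allele intervals
#'   `s_interval`, `l_interval`, and the input `genotypes`.
#' @export
gen_depth_profiles <- function(spec, genotypes, mean_depth = 60, noise_cv = 0.1,
                               seed = 1) {
  stopifnot(inherits(spec, "mnlp_allele_spec"))
  if (mean_depth <= 0) stop("'mean_depth' must be > 0")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  gts <- vapply(genotypes, normalize_genotype, character(1), USE.NAMES = FALSE)
  l_dos <- vapply(strsplit(gts, "/"), function(a) sum(a == "L"), numeric(1))
  s_dos <- 2 - l_dos
  fl <- nchar(spec$flank_left)
  len_s <- nchar(spec$seq_s); len_l <- nchar(spec$seq_l)
  ns <- fl + len_s + nchar(spec$flank_right)
  nl <- fl + len_l + nchar(spec$flank_right)
  with_seed(seed, {
    make <- function(nc, allele_len, dos) {
      m <- matrix(mean_depth, nrow = length(gts), ncol = nc)
      m[, fl + seq_len(allele_len)] <- mean_depth * dos / 2
      if (noise_cv > 0) {
        shp <- 1 / noise_cv^2
        m <- m * matrix(stats::rgamma(length(m), shape = shp, rate = shp),
                        nrow = nrow(m))
      }
      rownames(m) <- sprintf("S%04d", seq_along(gts))
      m
    }
    s_depth <- make(ns, len_s, s_dos)
    l_depth <- make(nl, len_l, l_dos)
    structure(list(s_depth = s_depth, l_depth = l_depth,
                   s_interval = c(fl, fl + len_s),
                   l_interval = c(fl, fl + len_l),
                   genotypes = gts),
              class = "depth_profiles")
  })
}

#' Build a small synthetic peak set
#'
#' Equal-width peaks laid out on one contig, a configurable subset flagged as
#' allelically imbalanced.
#'
#' @param n_peaks number of peaks.
#' @param n_imbalanced how many (the first ones) carry allelic imbalance.
#' @param width,gap peak width and spacing in bp.
#' @param contig contig name.
#' @return data.frame with `peak_id`, `contig`, `start`, `end` (0-based
#'   half-open) and logical `imbalanced`.
#' @export
synth_peaks <- function(n_peaks = 5, n_imbalanced = 1, width = 1000,
                        gap = 250000, contig = "chr5") {
  start <- 1000000 + (seq_len(n_peaks) - 1L) * gap
  data.frame(peak_id = sprintf("peak_%02d", seq_len(n_peaks)),
             contig = contig, start = start, end = start + width,
             imbalanced = seq_len(n_peaks) <= n_imbalanced,
             stringsAsFactors = FALSE)
}

#' Simulate haplotype-resolved allele-specific counts at peak sites
#'
#' Emulates the post-alignment output of an allele-specific read-counting
#' workflow: every individual is a heterozygous carrier by construction; per
#' site, the total read count is drawn from `depth_law` and the haplotype-A
#' count from a beta-binomial with the condition's overdispersion and with
#' `p = ase_p` for imbalanced peaks, `p = 0.5` otherwise.
#'
#' @param model a [population_model()] (supplies `ase_p`, `rho_normal`,
#'   `rho_tumor`).
#' @param n_individuals heterozygous individuals per condition (paired ids).
#' @param peaks peak table as from [synth_peaks()]; an `imbalanced` column
#'   marks peaks simulated at `ase_p`.
#' @param sites_per_peak heterozygous sites per peak (>= 1).
#' @param depth_law function(n) returning n positive integer totals; default
#'   negative binomial with mean 40 (size 10), floored at 1.
#' @param seed integer seed.
#' @param conditions conditions to simulate (default both).
#' @return data.frame with columns `individual`, `condition`, `peak_id`,
#'   `site_id`, `site_position`, `hapA_count`, `hapB_count`.
#' @export
gen_ase_counts <- function(model, n_individuals, peaks = synth_peaks(),
                           sites_per_peak = 3,
                           depth_law = function(n) pmax(1L, stats::rnbinom(n, mu = 40, size = 10)),
                           seed = 1,
                           conditions = c("normal", "tumor")) {
  stopifnot(inherits(model, "population_model"))
  if (sites_per_peak < 1L) stop("'sites_per_peak' must be >= 1")
  imb <- if ("imbalanced" %in% names(peaks)) peaks$imbalanced else rep(FALSE, nrow(peaks))
  rhos <- c(normal = model$rho_normal, tumor = model$rho_tumor)
  with_seed(seed, {
    rows <- list()
    for (cond in conditions) {
      for (pi in seq_len(nrow(peaks))) {
        pos <- round(seq(peaks$start[pi] + 1, peaks$end[pi] - 1,
                         length.out = sites_per_peak))
        p <- if (imb[pi]) model$ase_p else 0.5
        for (si in seq_len(sites_per_peak)) {
          ntot <- depth_law(n_individuals)
          ka <- rbetabinom(n_individuals, ntot, p, rhos[[cond]])
          rows[[length(rows) + 1L]] <- data.frame(
            individual = sprintf("ind%03d", seq_len(n_individuals)),
            condition = cond, peak_id = peaks$peak_id[pi],
            site_id = sprintf("%s_site%d", peaks$peak_id[pi], si),
            site_position = pos[si],
            hapA_count = as.integer(ka),
            hapB_count = as.integer(ntot - ka),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a cis SNP panel around a complex variant with GWAS Z-scores
#'
#' Haplotypes are mosaics of a small founder set (per-site founder switching
#' at `switch_rate` creates decaying LD); the complex-variant allele rides on
#' half of the founders, so panel SNPs tag it to varying degrees. GWAS
#' Z-scores are generated either analytically (`Z_j = r_{j,cv} z_cv + N(0,1)`
#' with `z_cv = gwas_beta * sqrt(gwas_n)`) or by logistic case-control
#' sampling; the mode used is recorded in the result. Monomorphic SNPs are
#' dropped with a message.
#'
#' @param model a [population_model()].
#' @param n_samples diploid reference-panel samples (the LD/training panel).
#' @param seed integer seed.
#' @param mode `"analytic"` (default) or `"sampled"`.
#' @param disease_prev baseline disease probability for `"sampled"` mode.
#' @return A list of class `cv_panel`: `snp_id`, `pos`, `haplotypes`
#'   (2n x m binary), `geno` (n x m dosages), `cv_dosage`, `r_cv`
#'   (per-SNP correlation with CV dosage), `ld` (SNP correlation matrix),
#'   `gwas_z`, `gwas_n`, `mode`, `n_dropped`.
#' @export
gen_cv_panel <- function(model, n_samples = 500, seed = 1,
                         mode = c("analytic", "sampled"),
                         disease_prev = 0.1) {
  stopifnot(inherits(model, "population_model"))
  mode <- match.arg(mode)
  m <- model$n_snps
  nf <- model$founder_count
  with_seed(seed, {
    freqs <- stats::runif(m, 0.1, 0.9)
    founders <- matrix(stats::rbinom(nf * m, 1L, rep(freqs, each = nf)),
                       nrow = nf, ncol = m)
    cv_idx <- m %/% 2L            # CV sits between SNP cv_idx and cv_idx + 1
    cv_founders <- sample.int(nf, max(1L, nf %/% 2L))
    loci <- m + 1L                # insert CV as pseudo-locus for copying
    fo_ext <- cbind(founders[, seq_len(cv_idx), drop = FALSE],
                    as.integer(seq_len(nf) %in% cv_founders),
                    founders[, (cv_idx + 1L):m, drop = FALSE])
    n_chrom <- 2L * n_samples
    haps_ext <- matrix(0L, nrow = n_chrom, ncol = loci)
    for (i in seq_len(n_chrom)) {
      sw <- c(TRUE, stats::runif(loci - 1L) < model$switch_rate)
      picks <- sample.int(nf, sum(sw), replace = TRUE)
      fid <- picks[cumsum(sw)]
      haps_ext[i, ] <- fo_ext[cbind(fid, seq_len(loci))]
    }
    cv_hap <- haps_ext[, cv_idx + 1L]
    haps <- haps_ext[, -(cv_idx + 1L), drop = FALSE]
    odd <- seq(1L, n_chrom, by = 2L)
    geno <- haps[odd, , drop = FALSE] + haps[odd + 1L, , drop = FALSE]
    cv_dosage <- cv_hap[odd] + cv_hap[odd + 1L]
    poly <- apply(geno, 2L, function(g) stats::var(g) > 0)
    n_dropped <- sum(!poly)
    if (n_dropped > 0L)
      message(sprintf("gen_cv_panel: dropped %d monomorphic SNPs", n_dropped))
    geno <- geno[, poly, drop = FALSE]
    haps <- haps[, poly, drop = FALSE]
    m_kept <- ncol(geno)
    if (m_kept < 2L) stop("fewer than 2 polymorphic SNPs in panel")
    if (stats::var(cv_dosage) == 0) stop("complex variant is monomorphic in panel")
    snp_id <- sprintf("snp_%03d", which(poly))
    pos <- 1000000L + which(poly) * 1000L
    ld <- stats::cor(geno)
    r_cv <- as.numeric(stats::cor(geno, cv_dosage))
    z_cv_true <- model$gwas_beta * sqrt(model$gwas_n)
    if (mode == "analytic") {
      # expected Z from LD with the causal CV, plus noise that is marginally
      # N(0,1) per SNP but jointly follows the LD correlation, as GWAS
      # summary statistics do
      ch <- chol(ld + diag(1e-6, m_kept))
      noise <- as.numeric(crossprod(ch, stats::rnorm(m_kept)))
      gwas_z <- r_cv * z_cv_true + noise
      gwas_n <- model$gwas_n
    } else {
      n_gwas <- min(model$gwas_n, 5000L)
      # fresh genotypes for the case-control sample, same founder process
      gh <- matrix(0L, nrow = 2L * n_gwas, ncol = loci)
      for (i in seq_len(2L * n_gwas)) {
        sw <- c(TRUE, stats::runif(loci - 1L) < model$switch_rate)
        picks <- sample.int(nf, sum(sw), replace = TRUE)
        fid <- picks[cumsum(sw)]
        gh[i, ] <- fo_ext[cbind(fid, seq_len(loci))]
      }
      og <- seq(1L, 2L * n_gwas, by = 2L)
      gcv <- gh[og, cv_idx + 1L] + gh[og + 1L, cv_idx + 1L]
      gg <- (gh[og, -(cv_idx + 1L), drop = FALSE] +
             gh[og + 1L, -(cv_idx + 1L), drop = FALSE])[, poly, drop = FALSE]
      eta <- stats::qlogis(disease_prev) +
        model$gwas_beta * sqrt(model$gwas_n / n_gwas) * scale(gcv)[, 1L]
      y <- stats::rbinom(n_gwas, 1L, stats::plogis(eta))
      r_gy <- as.numeric(stats::cor(gg, y))
      gwas_z <- r_gy * sqrt(n_gwas - 2) / sqrt(pmax(1e-12, 1 - r_gy^2))
      gwas_n <- n_gwas
    }
    structure(list(snp_id = snp_id, pos = pos, haplotypes = haps,
                   geno = geno, cv_dosage = cv_dosage, r_cv = r_cv,
                   ld = ld, gwas_z = gwas_z, gwas_n = gwas_n,
                   mode = mode, n_dropped = n_dropped),
              class = "cv_panel")
  })
}

#' @export
print.cv_panel <- function(x, ...) {
  cat(sprintf("Complex-variant panel: %d SNPs x %d samples (%s GWAS Z, n = %d)\n",
              length(x$snp_id), nrow(x$geno), x$mode, x$gwas_n))
  cat(sprintf("  CV allele frequency %.3f; best |r| with CV %.3f\n",
              mean(x$cv_dosage) / 2, max(abs(x$r_cv))))
  invisible(x)
}
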