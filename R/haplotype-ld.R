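# Two-locus haplotype estimation, LD statistics, the 3x3 SNP x MNLP genotype
# grid with recombinant classification, and genotype-trait association.

#' Estimate two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for an index SNP (alleles T/C)
#' crossed with the MNLP (alleles S/L) from unphased diploid dosages. Only
#' double heterozygotes are phase-ambiguous; the EM is initialized at linkage
#' equilibrium (products of observed allele frequencies) and iterates until
#' the largest frequency change falls below `tol`.
#'
#' @param cohort data.frame with `snp_dosage` (T count) and `mnlp_dosage`
#'   (L count); optionally phased columns `hap1`, `hap2` (labels like
#'   `"T-S"`).
#' @param tol convergence tolerance on the frequency change.
#' @param max_iter maximum EM iterations.
#' @param use_phase if `TRUE` and phase columns are present, return direct
#'   phased haplotype counts / 2n instead of running the EM.
#' @return Object of class `haplotype_freqs`: frequencies `TS`, `TL`, `CS`,
#'   `CL` plus `loglik`, `iterations`, `converged`.
#' @export
em_haplotype_freqs <- function(cohort, tol = 1e-8, max_iter = 1000,
                               use_phase = FALSE) {
  t_dos <- cohort$snp_dosage
  l_dos <- cohort$mnlp_dosage
  n <- length(t_dos)
  if (n < 2L) stop("need at least 2 samples")
  if (stats::var(t_dos) == 0 || stats::var(l_dos) == 0)
    stop("monomorphic locus: haplotype frequencies unidentifiable")
  if (use_phase) {
    if (!all(c("hap1", "hap2") %in% names(cohort)))
      stop("'use_phase = TRUE' requires hap1/hap2 columns")
    counts <- table(factor(c(cohort$hap1, cohort$hap2),
                           levels = c("T-S", "T-L", "C-S", "C-L")))
    f <- as.numeric(counts) / (2 * n)
    names(f) <- c("TS", "TL", "CS", "CL")
    return(structure(list(freqs = f, loglik = two_locus_loglik(f, t_dos, l_dos),
                          iterations = 0L, converged = TRUE),
                     class = "haplotype_freqs"))
  }
  # genotype category counts; s = S dosage = 2 - L dosage
  tab <- table(factor(t_dos, levels = 0:2), factor(l_dos, levels = 0:2))
  pT <- mean(t_dos) / 2
  pL <- mean(l_dos) / 2
  f <- c(TS = pT * (1 - pL), TL = pT * pL, CS = (1 - pT) * (1 - pL),
         CL = (1 - pT) * pL)
  n_dh <- tab["1", "1"]
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    # E-step: expected haplotype counts (fixed contributions + split of
    # double heterozygotes between T-S/C-L and T-L/C-S phasings)
    cTS <- 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"]
    cTL <- 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"]
    cCS <- 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"]
    cCL <- 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"]
    if (n_dh > 0) {
      wc <- f["TS"] * f["CL"]
      wr <- f["TL"] * f["CS"]
      w <- if (wc + wr > 0) wc / (wc + wr) else 0.5
      cTS <- cTS + n_dh * w; cCL <- cCL + n_dh * w
      cTL <- cTL + n_dh * (1 - w); cCS <- cCS + n_dh * (1 - w)
    }
    fnew <- stats::setNames(as.numeric(c(cTS, cTL, cCS, cCL)) / (2 * n),
                            c("TS", "TL", "CS", "CL"))
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  structure(list(freqs = f, loglik = two_locus_loglik(f, t_dos, l_dos),
                 iterations = it, converged = converged),
            class = "haplotype_freqs")
}

# log-likelihood of unphased genotype data under haplotype frequencies f
two_locus_loglik <- function(f, t_dos, l_dos) {
  f <- pmax(f, 0)
  p <- function(h1, h2) if (h1 == h2) f[h1]^2 else 2 * f[h1] * f[h2]
  probs <- matrix(0, 3, 3)   # [t+1, l+1]
  probs[1, 1] <- p("CS", "CS"); probs[1, 2] <- p("CS", "CL"); probs[1, 3] <- p("CL", "CL")
  probs[2, 1] <- p("TS", "CS"); probs[2, 3] <- p("TL", "CL")
  probs[2, 2] <- 2 * f["TS"] * f["CL"] + 2 * f["TL"] * f["CS"]
  probs[3, 1] <- p("TS", "TS"); probs[3, 2] <- p("TS", "TL"); probs[3, 3] <- p("TL", "TL")
  sum(log(pmax(probs[cbind(t_dos + 1L, l_dos + 1L)], 1e-300)))
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat("Two-locus haplotype frequencies (EM)\n")
  print(round(x$freqs, 4))
  cat(sprintf("  loglik %.3f after %d iterations (%sconverged)\n",
              x$loglik, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Linkage disequilibrium statistics from haplotype frequencies
#'
#' Computes `D = f_TS - p_T p_S`, the normalized `D' = |D| / D_max`, and
#' `r^2 = D^2 / (p_T p_C p_S p_L)`. For biallelic loci `r^2 <= D'^2` always
#' holds.
#'
#' @param freqs a [em_haplotype_freqs()] result, or a numeric length-4
#'   vector of frequencies in the order T-S, T-L, C-S, C-L.
#' @return List of class `ld_stats`: `D`, `D_prime`, `r2` and the allele
#'   frequencies `p_T`, `p_S`.
#' @examples
#' ld_stats(c(0.4, 0.1, 0.1, 0.4))  # D = 0.15, D' = 0.6, r2 = 0.36
#' @export
ld_stats <- function(freqs) {
  f <- if (inherits(freqs, "haplotype_freqs")) freqs$freqs else as.numeric(freqs)
  if (length(f) != 4L || any(f < -1e-12) || abs(sum(f) - 1) > 1e-6)
    stop("'freqs' must be four non-negative haplotype frequencies summing to 1")
  f <- pmax(f, 0)
  names(f) <- c("TS", "TL", "CS", "CL")
  pT <- f["TS"] + f["TL"]; pS <- f["TS"] + f["CS"]
  pC <- 1 - pT; pL <- 1 - pS
  if (pT <= 0 || pT >= 1 || pS <= 0 || pS >= 1)
    stop("fixed allele: LD undefined")
  D <- unname(f["TS"] - pT * pS)
  D_max <- if (D > 0) min(pT * pL, pC * pS) else min(pT * pS, pC * pL)
  structure(list(D = D,
                 D_prime = unname(abs(D) / D_max),
                 r2 = unname(D^2 / (pT * pC * pS * pL)),
                 p_T = unname(pT), p_S = unname(pS)),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD: D = %.4f, D' = %.4f, r2 = %.4f (p_T = %.3f, p_S = %.3f)\n",
              x$D, x$D_prime, x$r2, x$p_T, x$p_S))
  invisible(x)
}

#' Enumerate the nine SNP x MNLP genotype combinations
#'
#' The full 3x3 product of index-SNP genotypes {T/T, T/C, C/C} with MNLP
#' genotypes {S/S, S/L, L/L}, in stable row-major order.
#'
#' @return data.frame with columns `snp`, `mnlp` and a `label` combining
#'   both; nine rows.
#' @export
enumerate_genotype_combinations <- function() {
  grid <- expand.grid(mnlp = c("S/S", "S/L", "L/L"),
                      snp = c("T/T", "T/C", "C/C"),
                      stringsAsFactors = FALSE)[, c("snp", "mnlp")]
  grid$label <- paste(grid$snp, grid$mnlp, sep = " + ")
  rownames(grid) <- NULL
  grid
}

parse_genotype_alleles <- function(g) {
  a <- strsplit(toupper(gsub("[^A-Z/]", "", toupper(g))), "/")[[1]]
  if (length(a) != 2L || any(nchar(a) != 1L))
    stop(sprintf("invalid genotype '%s'", g))
  a
}

#' Classify a two-locus genotype as recombinant or parental
#'
#' Given the coupling phase of the locus (by default T with S and C with L),
#' counts the minimum number of non-coupling (recombinant) haplotypes over
#' all phase resolutions of the genotype pair. Double heterozygotes resolve
#' to zero because the coupling phasing is attainable; discordant double
#' homozygotes force two recombinant haplotypes.
#'
#' @param snp_genotype e.g. `"T/T"`.
#' @param mnlp_genotype e.g. `"S/L"`.
#' @param coupling the two coupling haplotypes, as `"X-Y"` strings pairing a
#'   first-locus allele with a second-locus allele.
#' @return List of class `recomb_class`: `category_label`,
#'   `min_recombinant_haplotypes` (0, 1 or 2) and `is_recombinant`.
#' @examples
#' classify_recombinant("T/T", "S/L")  # 1 recombinant haplotype
#' classify_recombinant("T/C", "S/L")  # 0: coupling resolution exists
#' @export
classify_recombinant <- function(snp_genotype, mnlp_genotype,
                                 coupling = c("T-S", "C-L")) {
  a <- parse_genotype_alleles(snp_genotype)
  b <- parse_genotype_alleles(mnlp_genotype)
  coup <- toupper(coupling)
  pairings <- list(c(paste(a[1], b[1], sep = "-"), paste(a[2], b[2], sep = "-")),
                   c(paste(a[1], b[2], sep = "-"), paste(a[2], b[1], sep = "-")))
  counts <- vapply(pairings, function(h) sum(!h %in% coup), numeric(1))
  k <- as.integer(min(counts))
  structure(list(category_label = paste(snp_genotype, mnlp_genotype, sep = " + "),
                 min_recombinant_haplotypes = k,
                 is_recombinant = k >= 1L),
            class = "recomb_class")
}

#' Pearson association between a trait and a genotype dosage
#'
#' @param trait numeric trait values (e.g. expression FPKM).
#' @param dosage numeric allele dosages (0/1/2).
#' @return List with `r`, `p_value` (two-sided, t distribution with n-2 df),
#'   `n` and `group_means` (mean trait per dosage class).
#' @export
genotype_trait_association <- function(trait, dosage) {
  if (length(trait) != length(dosage)) stop("length mismatch")
  if (length(trait) < 3L) stop("need at least 3 samples")
  if (stats::var(trait) == 0 || stats::var(dosage) == 0)
    stop("degenerate input: constant trait or dosage")
  ct <- stats::cor.test(trait, dosage, method = "pearson")
  gm <- tapply(trait, factor(dosage, levels = sort(unique(dosage))), mean)
  gm <- stats::setNames(as.numeric(gm), names(gm))
  list(r = unname(ct$estimate),
       p_value = max(ct$p.value, .Machine$double.xmin),
       n = length(trait),
       group_means = gm)
}

#' Compare the eQTL strength of the index SNP and the MNLP
#'
#' Reports the marginal Pearson correlation of each variant with the trait,
#' the partial correlation of each given the other (the recombinant-driven
#' quantity separating two linked variants), and trait means over the 3x3
#' genotype grid (e.g. T/T carriers split by MNLP genotype). When the two
#' dosages are essentially collinear (|r| >= 0.999), only marginals are
#' reported and the comparison is flagged inseparable.
#'
#' @param trait numeric trait values.
#' @param snp_dosage,mnlp_dosage numeric dosages (0/1/2).
#' @return List of class `eqtl_comparison`: `r_snp`, `r_mnlp`,
#'   `partial_r_snp` (SNP | MNLP), `partial_r_mnlp` (MNLP | SNP),
#'   `r_between`, `grid_means` (3x3 matrix, SNP rows x MNLP columns),
#'   `inseparable`.
#' @export
compare_eqtl_variants <- function(trait, snp_dosage, mnlp_dosage) {
  n <- length(trait)
  if (length(snp_dosage) != n || length(mnlp_dosage) != n) stop("length mismatch")
  if (stats::var(snp_dosage) == 0 || stats::var(mnlp_dosage) == 0)
    stop("both dosages must be polymorphic")
  r_s <- stats::cor(trait, snp_dosage)
  r_m <- stats::cor(trait, mnlp_dosage)
  r_b <- stats::cor(snp_dosage, mnlp_dosage)
  grid <- matrix(NA_real_, 3, 3,
                 dimnames = list(snp = c("0", "1", "2"), mnlp = c("0", "1", "2")))
  mm <- tapply(trait, list(factor(snp_dosage, levels = 0:2),
                           factor(mnlp_dosage, levels = 0:2)), mean)
  grid[] <- mm
  insep <- abs(r_b) >= 0.999
  pr <- function(rxy, rxz, rzy)
    (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
  structure(list(
    r_snp = r_s, r_mnlp = r_m, r_between = r_b,
    partial_r_snp = if (insep) NA_real_ else pr(r_s, r_b, r_m),
    partial_r_mnlp = if (insep) NA_real_ else pr(r_m, r_b, r_s),
    grid_means = grid, inseparable = insep, n = n),
    class = "eqtl_comparison")
}

#' @export
print.eqtl_comparison <- function(x, ...) {
  cat("eQTL comparison (index SNP vs MNLP)\n")
  cat(sprintf("  marginal r: SNP %.3f, MNLP %.3f (r between dosages %.3f)\n",
              x$r_snp, x$r_mnlp, x$r_between))
  if (x$inseparable) {
    cat("  dosages collinear: partial correlations not assessable\n")
  } else {
    cat(sprintf("  partial r: SNP | MNLP %.3f, MNLP | SNP %.3f\n",
                x$partial_r_snp, x$partial_r_mnlp))
  }
  invisible(x)
}
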