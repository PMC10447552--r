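#' Population model behind the synthetic cohorts
#'
#' Bundles every parameter the synthetic-data generators share: the four
#' two-locus haplotype frequencies (index-SNP allele T/C crossed with MNLP
#' allele S/L), the eQTL effect of the long allele on expression, the
#' beta-binomial overdispersion of allele-specific chromatin counts in normal
#' and tumor tissue, the haplotype allelic ratio of an imbalanced peak, and
#' the GWAS architecture of the complex-variant panel.
#'
#' Defaults emulate the study conditions of the prostate 5p15.33 locus: tight
#' coupling of the T risk allele with the S allele and of the protective C
#' allele with the L allele (D' ~ 0.87, r2 ~ 0.7 under the default
#' frequencies), an expression increase per L-allele copy, near-zero
#' overdispersion in normal tissue with slightly more in tumor (the order of
#' magnitude of typical per-individual estimates, ~5e-4 and ~3e-3), and an
#' allelic ratio of 0.9 for an imbalanced peak (about a ten-fold enrichment
#' of long-allele reads).
#'
#' @param hap_freqs numeric length-4 vector of haplotype frequencies in the
#'   order T-S, T-L, C-S, C-L; must be non-negative and sum to 1.
#' @param eqtl_beta expression shift per copy of the L allele.
#' @param expr_sd residual standard deviation of the expression trait.
#' @param rho_normal,rho_tumor beta-binomial overdispersion in `[0,1)` for
#'   the two conditions.
#' @param ase_p haplotype allelic ratio in (0,1) for imbalanced peaks.
#' @param gwas_beta disease effect per standardized unit of complex-variant
#'   dosage (drives the GWAS Z-scores of the panel).
#' @param gwas_n effective GWAS sample size.
#' @param n_snps number of cis SNPs in the complex-variant panel.
#' @param founder_count number of founder haplotypes used to build LD.
#' @param switch_rate per-site probability of switching founder during
#'   haplotype copying (controls LD decay).
#' @return An object of class `population_model`.
#' @export
population_model <- function(hap_freqs = c(TS = 0.42, TL = 0.03, CS = 0.05, CL = 0.50),
                             eqtl_beta = 1.0, expr_sd = 1.0,
                             rho_normal = 5e-4, rho_tumor = 2.7e-3,
                             ase_p = 0.9,
                             gwas_beta = 0.045, gwas_n = 50000,
                             n_snps = 100, founder_count = 10,
                             switch_rate = 0.01) {
  hap_freqs <- as.numeric(hap_freqs)
  if (length(hap_freqs) != 4L || anyNA(hap_freqs) || any(hap_freqs < 0))
    stop("'hap_freqs' must be four non-negative frequencies (T-S, T-L, C-S, C-L)")
  if (abs(sum(hap_freqs) - 1) > 1e-8)
    stop(sprintf("'hap_freqs' must sum to 1 (got %.6f)", sum(hap_freqs)))
  names(hap_freqs) <- c("TS", "TL", "CS", "CL")
  for (r in c(rho_normal = rho_normal, rho_tumor = rho_tumor))
    if (r < 0 || r >= 1) stop("overdispersion 'rho' must lie in [0, 1)")
  check_prob(ase_p, "ase_p", open_left = TRUE, open_right = TRUE)
  if (n_snps < 2L) stop("'n_snps' must be >= 2")
  if (founder_count < 2L) stop("'founder_count' must be >= 2")
  structure(list(hap_freqs = hap_freqs, eqtl_beta = eqtl_beta,
                 expr_sd = expr_sd, rho_normal = rho_normal,
                 rho_tumor = rho_tumor, ase_p = ase_p,
                 gwas_beta = gwas_beta, gwas_n = gwas_n,
                 n_snps = as.integer(n_snps),
                 founder_count = as.integer(founder_count),
                 switch_rate = switch_rate),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model\n")
  cat("  haplotype freqs (T-S, T-L, C-S, C-L):",
      paste(format(x$hap_freqs, digits = 3), collapse = ", "), "\n")
  cat(sprintf("  eQTL beta %.3g (sd %.3g); ASE p %.3g; rho N/T %.2g/%.2g\n",
              x$eqtl_beta, x$expr_sd, x$ase_p, x$rho_normal, x$rho_tumor))
  cat(sprintf("  GWAS beta %.3g at n = %d; panel: %d SNPs, %d founders, switch %.3g\n",
              x$gwas_beta, x$gwas_n, x$n_snps, x$founder_count, x$switch_rate))
  invisible(x)
}
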