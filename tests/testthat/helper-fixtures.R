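# Shared fixtures: everything is built in code at test time.

fx_spec <- mnlp_allele_spec()
fx_refs <- build_allele_references(fx_spec)
fx_model <- population_model()

# a read_classification with given counts, for call-threshold tests
make_classification <- function(n_s, n_l, n_ambiguous = 0, n_unmatched = 0) {
  structure(list(n_s = n_s, n_l = n_l, n_ambiguous = n_ambiguous,
                 n_unmatched = n_unmatched,
                 n_total = n_s + n_l + n_ambiguous + n_unmatched,
                 assignment = character(), read_types = table(character())),
            class = "read_classification")
}

# independent two-locus multinomial log-likelihood used as the EM oracle:
# cell probabilities computed from haplotype frequencies from first
# principles, no package internals
oracle_two_locus_loglik <- function(fTS, pT, pS, t_dos, l_dos) {
  fTL <- pT - fTS
  fCS <- pS - fTS
  fCL <- 1 - fTS - fTL - fCS
  f <- c(fTS, fTL, fCS, fCL)
  if (any(f < -1e-12)) return(-Inf)
  f <- pmax(f, 0)
  # haplotypes: 1 T-S, 2 T-L, 3 C-S, 4 C-L; genotype prob by enumeration
  tc <- c(1, 1, 0, 0); lc <- c(0, 1, 0, 1)
  probs <- matrix(0, 3, 3)
  for (h1 in 1:4) for (h2 in 1:4) {
    t <- tc[h1] + tc[h2]; l <- lc[h1] + lc[h2]
    probs[t + 1, l + 1] <- probs[t + 1, l + 1] + f[h1] * f[h2]
  }
  sum(log(pmax(probs[cbind(t_dos + 1, l_dos + 1)], 1e-300)))
}

# grid-search MLE over the single free haplotype frequency (marginals are
# fixed by the observed allele counts)
oracle_grid_haplotype_freqs <- function(t_dos, l_dos, step = 1e-4) {
  pT <- mean(t_dos) / 2
  pS <- 1 - mean(l_dos) / 2
  lo <- max(0, pT + pS - 1)
  hi <- min(pT, pS)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, oracle_two_locus_loglik, numeric(1),
               pT = pT, pS = pS, t_dos = t_dos, l_dos = l_dos)
  fTS <- grid[which.max(ll)]
  c(TS = fTS, TL = pT - fTS, CS = pS - fTS, CL = 1 - pT - pS + fTS)
}

# closed-form binomial likelihood-ratio statistic (single-observation oracle)
oracle_binom_lrt <- function(k, n) {
  phat <- k / n
  2 * (stats::dbinom(k, n, max(min(phat, 1 - 1e-12), 1e-12), log = TRUE) -
       stats::dbinom(k, n, 0.5, log = TRUE))
}

# Wilson score interval evaluated from the closed form
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(center - half, center + half)
}
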