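# Haplotype beta-binomial allelic-imbalance (chromatin QTL) framework:
# per-individual overdispersion, peak-level count merging, variant-to-peak
# assignment, combined and differential likelihood-ratio tests, BH FDR and
# peak flagging.

#' Estimate beta-binomial overdispersion for one individual/experiment
#'
#' Maximizes the joint beta-binomial likelihood of the individual's
#' peak-level counts over `rho` with the allelic proportion fixed at the
#' null value 0.5 (null-anchored estimation), on the bounded interval
#' `[0, 0.999]`. Boundary maxima are reported as converged.
#'
#' @param k haplotype-A counts, one per peak-level observation.
#' @param n totals.
#' @param individual,condition identifiers carried into the result.
#' @return List of class `overdispersion_estimate`: `rho_hat`,
#'   `n_observations`, `converged`, `note`.
#' @export
estimate_overdispersion <- function(k, n, individual = NA_character_,
                                    condition = NA_character_) {
  if (length(k) != length(n)) stop("length mismatch")
  if (any(k < 0) || any(k > n) || any(n < 1)) stop("invalid counts")
  out <- function(rho, conv, note = NA_character_) structure(
    list(individual = individual, condition = condition, rho_hat = rho,
         n_observations = length(k), converged = conv, note = note),
    class = "overdispersion_estimate")
  if (length(k) < 2L) return(out(0, FALSE, "unidentifiable"))
  nll <- function(rho) -sum(betabinom_loglik(k, n, 0.5, rho))
  opt <- stats::optimize(nll, c(1e-9, 0.999))
  cand <- c(0, opt$minimum, 0.999)
  vals <- vapply(cand, nll, numeric(1))
  out(cand[which.min(vals)], TRUE)
}

#' @export
print.overdispersion_estimate <- function(x, ...) {
  cat(sprintf("Overdispersion rho_hat = %.3g (%d observations%s)\n",
              x$rho_hat, x$n_observations,
              if (is.na(x$note)) "" else paste0("; ", x$note)))
  invisible(x)
}

#' Per-individual overdispersion across an allele-specific count table
#'
#' Applies [estimate_overdispersion()] to each individual x condition using
#' the peak-level merged counts.
#'
#' @param table an allele-specific count table (see [gen_ase_counts()]).
#' @return data.frame with `individual`, `condition`, `rho_hat`,
#'   `n_observations`, `converged`.
#' @export
estimate_overdispersion_all <- function(table) {
  merged <- merge_peak_counts(table)
  groups <- split(merged, list(merged$individual, merged$condition), drop = TRUE)
  do.call(rbind, lapply(groups, function(g) {
    e <- estimate_overdispersion(g$K, g$N, g$individual[1], g$condition[1])
    data.frame(individual = e$individual, condition = e$condition,
               rho_hat = e$rho_hat, n_observations = e$n_observations,
               converged = e$converged, stringsAsFactors = FALSE)
  }))
}

#' Merge haplotype-specific counts across a peak's heterozygous sites
#'
#' For each (individual, condition, peak) the haplotype-A and total counts
#' are summed over all read-carrying sites, giving a single measure of
#' allele specificity per peak.
#'
#' @param table data.frame with `individual`, `condition`, `peak_id`,
#'   `hapA_count`, `hapB_count`.
#' @return data.frame with `individual`, `condition`, `peak_id`, `K`
#'   (haplotype-A), `N` (total).
#' @export
merge_peak_counts <- function(table) {
  need <- c("individual", "condition", "peak_id", "hapA_count", "hapB_count")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  agg <- stats::aggregate(
    cbind(K = table$hapA_count, N = table$hapA_count + table$hapB_count),
    by = list(individual = table$individual, condition = table$condition,
              peak_id = table$peak_id),
    FUN = sum)
  agg[order(agg$peak_id, agg$condition, agg$individual), , drop = FALSE]
}

#' Pair variants with peaks within a distance window
#'
#' A (peak, variant) test unit is formed when the variant lies within
#' `max_dist` of the peak center (inclusive boundary; center = floor
#' midpoint) and at least one individual is heterozygous for the variant.
#'
#' @param variants data.frame with `variant_id`, `pos`, optionally `contig`,
#'   and `het_individuals` (list-column or comma-separated string of
#'   heterozygous carriers).
#' @param peaks data.frame with `peak_id`, `start`, `end`, optionally
#'   `contig` (0-based half-open).
#' @param max_dist assignment window around the peak center, in bp.
#' @return data.frame with `peak_id`, `variant_id`, `distance`.
#' @export
assign_variants_to_peaks <- function(variants, peaks, max_dist = 100000) {
  centers <- (peaks$start + peaks$end) %/% 2L
  het_n <- vapply(seq_len(nrow(variants)), function(i) {
    h <- variants$het_individuals[[i]]
    if (is.character(h) && length(h) == 1L)
      h <- strsplit(h, ",", fixed = TRUE)[[1]]
    length(h[nzchar(h)])
  }, numeric(1))
  out <- list()
  for (pi in seq_len(nrow(peaks))) {
    for (vi in seq_len(nrow(variants))) {
      if (!is.null(variants$contig) && !is.null(peaks$contig) &&
          variants$contig[vi] != peaks$contig[pi]) next
      d <- abs(variants$pos[vi] - centers[pi])
      if (d <= max_dist && het_n[vi] >= 1L)
        out[[length(out) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[pi], variant_id = variants$variant_id[vi],
          distance = d, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(peak_id = character(), variant_id = character(),
                      distance = numeric()))
  do.call(rbind, out)
}

# joint log-likelihood across individuals at a shared p (grouped by rho so
# the vectorized density is used)
joint_loglik <- function(p, K, N, rho) {
  s <- 0
  for (r in unique(rho)) {
    i <- rho == r
    s <- s + sum(betabinom_loglik(K[i], N[i], p, r))
  }
  s
}

max_joint_loglik <- function(K, N, rho) {
  opt <- stats::optimize(function(p) -joint_loglik(p, K, N, rho),
                         c(1e-6, 1 - 1e-6))
  # golden-section can stall near the boundary; also try the endpoints and
  # the pooled moment estimate
  cand <- unique(c(opt$minimum, 1e-6, 1 - 1e-6,
                   min(max(sum(K) / sum(N), 1e-6), 1 - 1e-6)))
  ll <- vapply(cand, joint_loglik, numeric(1), K = K, N = N, rho = rho)
  best <- which.max(ll)
  list(p_hat = cand[best], loglik = ll[best])
}

# Exact finite-sample p-value for the combined imbalance LRT by enumerating
# all count configurations under H0 (p = 0.5, per-individual rho). The LRT
# statistic over configurations is computed on a fixed p grid so that the
# ordering is consistent; used only when the configuration space is small.
exact_imbalance_pvalue <- function(K, N, rho, grid_n = 201, max_configs = 20000) {
  n_cfg <- prod(N + 1)
  if (n_cfg > max_configs) return(NULL)
  grid <- seq(1 / (2 * grid_n), 1 - 1 / (2 * grid_n), length.out = grid_n)
  cfg <- as.matrix(expand.grid(lapply(N, function(x) 0:x)))
  lp0 <- 0
  ll_grid <- matrix(0, nrow = n_cfg, ncol = grid_n)
  for (i in seq_along(N)) {
    tab0 <- betabinom_loglik(0:N[i], N[i], 0.5, rho[i])
    lp0 <- lp0 + tab0[cfg[, i] + 1L]
    tabg <- sapply(grid, function(p) betabinom_loglik(0:N[i], N[i], p, rho[i]))
    ll_grid <- ll_grid + tabg[cfg[, i] + 1L, , drop = FALSE]
  }
  stat_cfg <- 2 * (apply(ll_grid, 1L, max) - lp0)
  obs <- which(colSums(t(cfg) == K) == length(K))
  p_obs <- stat_cfg[obs[1]]
  sum(exp(lp0)[stat_cfg >= p_obs - 1e-9])
}

new_imbalance_result <- function(peak_id, variant_id, category, n_ind,
                                 p_hat, lrt, p_value, method) {
  structure(list(peak_id = peak_id, variant_id = variant_id,
                 category = category, n_het_individuals = n_ind,
                 p_hat = p_hat, lrt_stat = lrt, p_value = p_value,
                 method = method),
            class = "imbalance_result")
}

#' @export
print.imbalance_result <- function(x, ...) {
  cat(sprintf("Allelic imbalance [%s]: p_hat = %.3f, LRT = %.3f, p = %.3g (%s, %d individuals)\n",
              x$category, if (is.null(x$p_hat)) NA else x$p_hat,
              x$lrt_stat, x$p_value, x$method, x$n_het_individuals))
  invisible(x)
}

#' Combined haplotype beta-binomial test for allelic imbalance
#'
#' All heterozygous individuals are tested together under the expectation of
#' a consistent allele-specific effect: H0 fixes the allelic proportion at
#' 0.5 for every individual (each with its own overdispersion), H1 fits one
#' shared proportion by maximum likelihood. The statistic is
#' `2 (l1 - l0)` with a 1-df chi-square p-value; when the total read count
#' is below `exact_total` and the configuration space is small, an exact
#' enumeration p-value replaces the asymptotic one.
#'
#' @param K per-individual merged haplotype-A counts.
#' @param N per-individual merged totals.
#' @param rho per-individual overdispersion (scalar recycled).
#' @param category test category label (`"normal"`, `"tumor"` or `"both"`).
#' @param peak_id,variant_id identifiers carried into the result.
#' @param exact_total total-count threshold below which the exact
#'   enumeration p-value is used.
#' @return An `imbalance_result` with `p_hat`, `lrt_stat`, `p_value`.
#' @export
test_imbalance <- function(K, N, rho = 0, category = "normal",
                           peak_id = NA_character_, variant_id = NA_character_,
                           exact_total = 20) {
  if (length(K) != length(N)) stop("length mismatch")
  keep <- N >= 1
  K <- K[keep]; N <- N[keep]
  rho <- rep_len(rho, length(K))
  if (length(K) == 0L || sum(N) == 0) stop("no individuals with reads")
  l0 <- joint_loglik(0.5, K, N, rho)
  fit <- max_joint_loglik(K, N, rho)
  lrt <- max(0, 2 * (fit$loglik - l0))
  method <- "chisq"
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (sum(N) < exact_total) {
    pe <- exact_imbalance_pvalue(K, N, rho)
    if (!is.null(pe)) { p <- min(1, pe); method <- "exact" }
  }
  new_imbalance_result(peak_id, variant_id, category, length(K),
                       fit$p_hat, lrt, p, method)
}

#' Differential allelic-imbalance test between tumor and normal
#'
#' H0 fits a single shared allelic proportion across both conditions; H1
#' fits separate tumor and normal proportions (per-individual overdispersion
#' under both). 1-df chi-square p-value; the hypotheses leave the shared
#' proportion free, so the asymptotic p-value is used at all sample sizes.
#'
#' @param K_tumor,N_tumor,K_normal,N_normal merged counts per condition.
#' @param rho_tumor,rho_normal per-individual overdispersion (recycled).
#' @param peak_id,variant_id identifiers.
#' @return An `imbalance_result` with category `"differential"`; `p_hat` is
#'   a list with the two condition estimates.
#' @export
test_differential <- function(K_tumor, N_tumor, K_normal, N_normal,
                              rho_tumor = 0, rho_normal = 0,
                              peak_id = NA_character_,
                              variant_id = NA_character_) {
  if (length(K_tumor) == 0L || length(K_normal) == 0L)
    stop("both conditions need at least one individual")
  rho_t <- rep_len(rho_tumor, length(K_tumor))
  rho_n <- rep_len(rho_normal, length(K_normal))
  fit_t <- max_joint_loglik(K_tumor, N_tumor, rho_t)
  fit_n <- max_joint_loglik(K_normal, N_normal, rho_n)
  fit_0 <- max_joint_loglik(c(K_tumor, K_normal), c(N_tumor, N_normal),
                            c(rho_t, rho_n))
  lrt <- max(0, 2 * (fit_t$loglik + fit_n$loglik - fit_0$loglik))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  res <- new_imbalance_result(peak_id, variant_id, "differential",
                              length(K_tumor) + length(K_normal),
                              NULL, lrt, p, "chisq")
  res$p_hat <- list(tumor = fit_t$p_hat, normal = fit_n$p_hat,
                    shared = fit_0$p_hat)
  res
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up BH adjustment with significance flags at the given
#' false-discovery rate.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param q target FDR (default 0.10).
#' @return data.frame with `p_value`, `q_value`, `significant`.
#' @export
fdr_bh <- function(p_values, q = 0.10) {
  if (length(p_values) == 0L)
    return(data.frame(p_value = numeric(), q_value = numeric(),
                      significant = logical()))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p_values, method = "BH")
  data.frame(p_value = p_values, q_value = qv, significant = qv <= q)
}

#' Flag peaks as imbalanced per test category
#'
#' A peak is flagged in a category iff any of its (peak, variant) tests is
#' significant at the FDR threshold in that category; categories are
#' independent.
#'
#' @param results data.frame with `peak_id`, `category`, `q_value`.
#' @param q FDR threshold.
#' @return data.frame with `peak_id`, `category`, `flagged`.
#' @export
call_imbalanced_peaks <- function(results, q = 0.10) {
  need <- c("peak_id", "category", "q_value")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  agg <- stats::aggregate(results$q_value <= q,
                          by = list(peak_id = results$peak_id,
                                    category = results$category),
                          FUN = any)
  names(agg)[3] <- "flagged"
  agg[order(agg$peak_id, agg$category), , drop = FALSE]
}

#' Run the full allelic-imbalance analysis on a count table
#'
#' Merges counts per peak, estimates per-individual overdispersion
#' (null-anchored), runs the combined test per peak for the normal, tumor
#' and pooled ("both") categories plus the tumor-vs-normal differential
#' test, applies BH FDR within each category, and flags imbalanced peaks.
#'
#' @param table an allele-specific count table (see [gen_ase_counts()]).
#' @param q FDR threshold (default 0.10).
#' @param categories subset of `c("normal", "tumor", "both",
#'   "differential")`.
#' @return List of class `ase_analysis`: `results` (per peak x category
#'   tests with q-values), `peak_flags`, `overdispersion`.
#' @export
run_ase_analysis <- function(table, q = 0.10,
                             categories = c("normal", "tumor", "both",
                                            "differential")) {
  merged <- merge_peak_counts(table)
  od <- estimate_overdispersion_all(table)
  rho_of <- function(ind, cond) {
    i <- match(paste(ind, cond), paste(od$individual, od$condition))
    ifelse(is.na(i), 0, od$rho_hat[i])
  }
  merged$rho <- rho_of(merged$individual, merged$condition)
  rows <- list()
  for (pk in unique(merged$peak_id)) {
    sub <- merged[merged$peak_id == pk, , drop = FALSE]
    nrm <- sub[sub$condition == "normal", , drop = FALSE]
    tmr <- sub[sub$condition == "tumor", , drop = FALSE]
    add <- function(res) rows[[length(rows) + 1L]] <<- data.frame(
      peak_id = pk, variant_id = pk, category = res$category,
      n_het_individuals = res$n_het_individuals, lrt_stat = res$lrt_stat,
      p_value = res$p_value, stringsAsFactors = FALSE)
    if ("normal" %in% categories && nrow(nrm) > 0)
      add(test_imbalance(nrm$K, nrm$N, nrm$rho, "normal", pk, pk))
    if ("tumor" %in% categories && nrow(tmr) > 0)
      add(test_imbalance(tmr$K, tmr$N, tmr$rho, "tumor", pk, pk))
    if ("both" %in% categories && nrow(sub) > 0)
      add(test_imbalance(sub$K, sub$N, sub$rho, "both", pk, pk))
    if ("differential" %in% categories && nrow(nrm) > 0 && nrow(tmr) > 0)
      add(test_differential(tmr$K, tmr$N, nrm$K, nrm$N, tmr$rho, nrm$rho,
                            pk, pk))
  }
  results <- do.call(rbind, rows)
  results$q_value <- NA_real_
  results$significant <- NA
  for (cat in unique(results$category)) {
    sel <- results$category == cat
    adj <- fdr_bh(results$p_value[sel], q)
    results$q_value[sel] <- adj$q_value
    results$significant[sel] <- adj$significant
  }
  structure(list(results = results,
                 peak_flags = call_imbalanced_peaks(results, q),
                 overdispersion = od, fdr = q),
            class = "ase_analysis")
}

#' @export
print.ase_analysis <- function(x, ...) {
  cat(sprintf("Allelic-imbalance analysis: %d tests across %d peaks (FDR %.2f)\n",
              nrow(x$results), length(unique(x$results$peak_id)), x$fdr))
  flg <- x$peak_flags[x$peak_flags$flagged, , drop = FALSE]
  if (nrow(flg)) {
    cat("  imbalanced peaks:\n")
    for (i in seq_len(nrow(flg)))
      cat(sprintf("    %s [%s]\n", flg$peak_id[i], flg$category[i]))
  } else cat("  no imbalanced peaks at this FDR\n")
  invisible(x)
}
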