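# TWAS-style complex-variant association: cross-validated genetic prediction
# of CV dosage, summary-statistic association, LD-based conditioning and
# approximate-Bayes-factor colocalization.

#' Train a cross-validated genetic predictor of complex-variant dosage
#'
#' Regresses CV dosage on standardized cis-SNP dosages. The default family
#' is ridge regression with the penalty chosen by inner cross-validation;
#' predictive accuracy is assessed by outer k-fold cross-validation
#' (out-of-sample r2 can be negative) with a correlation-test p-value, and
#' the reported weights are refit on the full data.
#'
#' @param panel a [gen_cv_panel()] result, or a list with `geno` (n x m
#'   dosage matrix), `cv_dosage` and `snp_id`.
#' @param folds outer cross-validation folds.
#' @param seed integer seed controlling fold assignment.
#' @param method `"ridge"` (default), `"elastic_net"` (alpha = 0.5) or
#'   `"top1"` (single best-tagging SNP).
#' @return List of class `cv_weights`: `snp_id`, `weights` (per standardized
#'   SNP), `training_r2`, `cv_r2`, `cv_p`, `method`.
#' @export
fit_cv_predictor <- function(panel, folds = 5, seed = 1,
                             method = c("ridge", "elastic_net", "top1")) {
  method <- match.arg(method)
  geno <- as.matrix(panel$geno)
  y <- as.numeric(panel$cv_dosage)
  n <- nrow(geno)
  if (n < 50L) stop("need at least 50 training samples")
  if (ncol(geno) < 2L) stop("need at least 2 SNPs")
  if (stats::var(y) == 0) stop("constant CV dosage: nothing to predict")
  X <- scale(geno)
  alpha <- switch(method, ridge = 0, elastic_net = 0.5, top1 = NA)
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(folds), n))
    fit_on <- function(idx) {
      if (method == "top1") {
        j <- which.max(abs(stats::cor(X[idx, , drop = FALSE], y[idx])))
        b <- stats::cov(X[idx, j], y[idx]) / stats::var(X[idx, j])
        w <- numeric(ncol(X)); w[j] <- b
        list(w = w, a = mean(y[idx]) - b * mean(X[idx, j]))
      } else {
        inner_id <- sample(rep_len(seq_len(folds), length(idx)))
        cvf <- glmnet::cv.glmnet(X[idx, , drop = FALSE], y[idx],
                                 alpha = alpha, foldid = inner_id,
                                 standardize = FALSE)
        cf <- as.numeric(stats::coef(cvf, s = "lambda.min"))
        list(w = cf[-1], a = cf[1])
      }
    }
    preds <- numeric(n)
    for (f in seq_len(folds)) {
      idx <- which(foldid != f)
      m <- fit_on(idx)
      hold <- which(foldid == f)
      preds[hold] <- m$a + X[hold, , drop = FALSE] %*% m$w
    }
    cv_r2 <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
    cv_p <- if (stats::var(preds) > 0)
      stats::cor.test(preds, y)$p.value else 1
    full <- fit_on(seq_len(n))
    fitted <- full$a + as.numeric(X %*% full$w)
    training_r2 <- if (stats::var(fitted) > 0) stats::cor(fitted, y)^2 else 0
    w <- full$w
    names(w) <- panel$snp_id
    structure(list(snp_id = panel$snp_id, weights = w,
                   training_r2 = training_r2, cv_r2 = cv_r2, cv_p = cv_p,
                   method = method,
                   center = attr(X, "scaled:center"),
                   scale = attr(X, "scaled:scale")),
              class = "cv_weights")
  })
}

#' @export
print.cv_weights <- function(x, ...) {
  cat(sprintf("CV genetic predictor (%s): training r2 = %.3f, CV r2 = %.3f (p = %.3g)\n",
              x$method, x$training_r2, x$cv_r2, x$cv_p))
  invisible(x)
}

get_weights <- function(weights) {
  if (inherits(weights, "cv_weights")) weights$weights else as.numeric(weights)
}

#' TWAS-style association of predicted CV dosage with the GWAS trait
#'
#' Combines per-SNP GWAS Z-scores with predictor weights through the LD
#' matrix: `z_cv = w'z / sqrt(w'Rw)`, with a two-sided normal p-value. Also
#' reports the top GWAS SNP and the signal-equivalence test between the
#' predicted-CV association and that SNP.
#'
#' @param weights a [fit_cv_predictor()] result or numeric weight vector.
#' @param z per-SNP GWAS Z-scores.
#' @param R SNP LD (correlation) matrix.
#' @param snp_id optional SNP identifiers.
#' @return List of class `twas_result`: `z_cv`, `p_value`, `top_snp_id`,
#'   `top_snp_z`, `r_top` (correlation between the predicted score and the
#'   top SNP), `equiv_stat`, `equiv_p`.
#' @export
twas_associate <- function(weights, z, R, snp_id = NULL) {
  w <- get_weights(weights)
  if (length(w) != length(z) || nrow(R) != length(z) || ncol(R) != length(z))
    stop("dimension mismatch between weights, z and R")
  wRw <- as.numeric(t(w) %*% R %*% w)
  if (wRw <= 1e-12) stop("degenerate weights: w'Rw ~ 0")
  z_cv <- sum(w * z) / sqrt(wRw)
  p <- 2 * stats::pnorm(-abs(z_cv))
  top <- which.max(abs(z))
  r_top <- as.numeric(R %*% w)[top] / sqrt(wRw)
  eq <- if (abs(r_top) < 1 - 1e-12)
    equivalence_test(z_cv, z[top], r_top)
  else list(stat = NA_real_, p = NA_real_)
  structure(list(z_cv = z_cv, p_value = p,
                 top_snp_id = if (is.null(snp_id)) top else snp_id[top],
                 top_snp_z = z[top], r_top = r_top,
                 equiv_stat = eq$stat, equiv_p = eq$p),
            class = "twas_result")
}

#' @export
print.twas_result <- function(x, ...) {
  cat(sprintf("TWAS-style CV association: z = %.3f (p = %.3g)\n", x$z_cv, x$p_value))
  cat(sprintf("  top GWAS SNP %s: z = %.3f; equivalence p = %.3g\n",
              as.character(x$top_snp_id), x$top_snp_z, x$equiv_p))
  invisible(x)
}

#' Condition GWAS Z-scores on the predicted complex variant
#'
#' For each SNP j, the correlation between the SNP and the predicted CV
#' score is `r_j = (Rw)_j / sqrt(w'Rw)` and the conditional Z-score is
#' `(z_j - r_j z_cv) / sqrt(1 - r_j^2)`. SNPs nearly collinear with the
#' score (|r| > 0.99) are reported as not assessable.
#'
#' @inheritParams twas_associate
#' @return data.frame with `snp_id`, `z`, `r_cv`, `z_cond`, `assessable`.
#' @export
condition_on_cv <- function(z, R, weights, snp_id = NULL) {
  w <- get_weights(weights)
  if (length(w) != length(z)) stop("dimension mismatch")
  wRw <- as.numeric(t(w) %*% R %*% w)
  if (wRw <= 1e-12) stop("degenerate weights: w'Rw ~ 0")
  z_cv <- sum(w * z) / sqrt(wRw)
  r <- as.numeric(R %*% w) / sqrt(wRw)
  ok <- abs(r) <= 0.99
  z_cond <- ifelse(ok, (z - r * z_cv) / sqrt(pmax(1e-12, 1 - r^2)), NA_real_)
  data.frame(snp_id = snp_id %||% seq_along(z), z = z, r_cv = r,
             z_cond = z_cond, assessable = ok, stringsAsFactors = FALSE)
}

#' Approximate-Bayes-factor colocalization of two association signals
#'
#' Wakefield approximate Bayes factors per SNP and trait
#' (`log ABF = 0.5 log(1 - r) + 0.5 z^2 r`, `r = W / (W + 1/n)`, `W` the
#' prior effect variance), combined over the five causal configurations
#' H0 (no association) through H4 (shared causal variant) with the usual
#' per-SNP priors.
#'
#' @param z_trait1,z_trait2 per-SNP Z-scores for the two traits (same SNPs).
#' @param n1,n2 effective sample sizes.
#' @param priors `(p1, p2, p12)`: prior probability that a SNP is causal for
#'   trait 1, trait 2, or both.
#' @param prior_sd prior effect standard deviations for the two traits.
#' @return List of class `coloc_result`: `pp` (PP0..PP4, summing to 1),
#'   `priors`, `n_snps`.
#' @export
coloc_abf <- function(z_trait1, z_trait2, n1, n2,
                      priors = c(1e-4, 1e-4, 1e-5),
                      prior_sd = c(0.15, 0.15)) {
  if (length(z_trait1) != length(z_trait2))
    stop("mismatched SNP sets between the two traits")
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  labf <- function(z, n, sd0) {
    r <- sd0^2 / (sd0^2 + 1 / n)
    0.5 * log(1 - r) + 0.5 * z^2 * r
  }
  l1 <- labf(z_trait1, n1, prior_sd[1])
  l2 <- labf(z_trait2, n2, prior_sd[2])
  p1 <- priors[1]; p2 <- priors[2]; p12 <- priors[3]
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  lh0 <- 0
  lh1 <- log(p1) + lsum1
  lh2 <- log(p2) + lsum2
  # sum over i != j of exp(l1_i + l2_j)
  a <- lsum1 + lsum2
  lh3 <- log(p1) + log(p2) +
    if (lsum12 - a > -1e-12) -Inf else a + log1p(-exp(lsum12 - a))
  lh4 <- log(p12) + lsum12
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, priors = priors, prior_sd = prior_sd,
                 n_snps = length(z_trait1)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization posteriors:\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Signal-equivalence test between the predicted CV and a SNP
#'
#' Tests whether two correlated association Z-scores are statistically
#' indistinguishable: `stat = (z_cv - z_top) / sqrt(2 (1 - r))`, two-sided
#' normal p. A high p-value means the two signals cannot be separated.
#'
#' @param z_cv predicted-CV association Z.
#' @param z_top comparison (top GWAS SNP) Z.
#' @param r_between correlation between the two association statistics
#'   (|r| < 1).
#' @return List with `stat` and `p`.
#' @export
equivalence_test <- function(z_cv, z_top, r_between) {
  if (abs(r_between) >= 1) {
    if (abs(z_cv - z_top) > 1e-8)
      stop("inconsistent input: perfectly correlated signals with different z")
    return(list(stat = 0, p = 1))
  }
  stat <- (z_cv - z_top) / sqrt(2 * (1 - r_between))
  list(stat = stat, p = 2 * stats::pnorm(-abs(stat)))
}

#' End-to-end complex-variant TWAS analysis of a panel
#'
#' Fits the genetic predictor, associates it with the GWAS trait, conditions
#' the per-SNP Z-scores on the predicted CV, and colocalizes the GWAS signal
#' with the panel-derived CV-QTL signal (`z_j = r_{j,cv} sqrt(n-2) /
#' sqrt(1 - r_{j,cv}^2)`).
#'
#' @param panel a [gen_cv_panel()] result.
#' @param folds,seed,method passed to [fit_cv_predictor()].
#' @param coloc_priors,coloc_sd passed to [coloc_abf()].
#' @return List of class `cv_twas`: `weights`, `twas`, `conditional`,
#'   `coloc`.
#' @export
cv_twas <- function(panel, folds = 5, seed = 1, method = "ridge",
                    coloc_priors = c(1e-4, 1e-4, 1e-5),
                    coloc_sd = c(0.15, 0.15)) {
  wts <- fit_cv_predictor(panel, folds = folds, seed = seed, method = method)
  tw <- twas_associate(wts, panel$gwas_z, panel$ld, snp_id = panel$snp_id)
  cond <- condition_on_cv(panel$gwas_z, panel$ld, wts, snp_id = panel$snp_id)
  n_ref <- nrow(panel$geno)
  r_cv <- pmin(0.9999, pmax(-0.9999, panel$r_cv))
  z_qtl <- r_cv * sqrt(n_ref - 2) / sqrt(1 - r_cv^2)
  cl <- coloc_abf(panel$gwas_z, z_qtl, panel$gwas_n, n_ref,
                  priors = coloc_priors, prior_sd = coloc_sd)
  structure(list(weights = wts, twas = tw, conditional = cond, coloc = cl),
            class = "cv_twas")
}

#' @export
print.cv_twas <- function(x, ...) {
  print(x$weights); print(x$twas)
  cat(sprintf("  PP4 (shared causal variant) = %.3f\n", x$coloc$pp["PP4"]))
  invisible(x)
}
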