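#' Beta-binomial log-likelihood in the (p, rho) parameterization
#'
#' The beta-binomial distribution with success probability `p` and
#' intraclass-correlation overdispersion `rho` corresponds to shape
#' parameters `a = p(1/rho - 1)`, `b = (1-p)(1/rho - 1)`. Its variance is
#' `n p (1-p) (1 + (n-1) rho)`; at `rho = 0` it reduces exactly to the
#' binomial distribution, which is what this function returns in that limit.
#'
#' @param k successes (haplotype-A read counts), vectorized.
#' @param n totals, vectorized along with `k`.
#' @param p success probability in (0,1).
#' @param rho overdispersion in `[0,1)`.
#' @return Log-density values, one per observation.
#' @examples
#' betabinom_loglik(3, 10, 0.5, 0)      # == dbinom(3, 10, 0.5, log = TRUE)
#' betabinom_loglik(12, 40, 0.3, 0.05)
#' @export
betabinom_loglik <- function(k, n, p, rho) {
  check_prob(p, "p", open_left = TRUE, open_right = TRUE)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  if (any(k < 0) || any(k > n) || any(n < 1))
    stop("counts must satisfy 0 <= k <= n, n >= 1")
  if (rho == 0) return(stats::dbinom(k, n, p, log = TRUE))
  a <- p * (1 / rho - 1)
  b <- (1 - p) * (1 / rho - 1)
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Draw beta-binomial counts
#'
#' @inheritParams betabinom_loglik
#' @param nobs number of draws.
#' @param size totals (scalar or length `nobs`).
#' @return Integer vector of counts.
#' @export
rbetabinom <- function(nobs, size, p, rho) {
  check_prob(p, "p", open_left = TRUE, open_right = TRUE)
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  size <- rep_len(size, nobs)
  if (rho == 0) return(stats::rbinom(nobs, size, p))
  a <- p * (1 / rho - 1)
  b <- (1 - p) * (1 / rho - 1)
  stats::rbinom(nobs, size, stats::rbeta(nobs, a, b))
}
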