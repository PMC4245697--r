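#' Likelihood-ratio test of QTL existence
#'
#' Tests the null hypothesis that the three QTL genotype means are equal
#' (no QTL associated with the phenotype) against the alternative that at
#' least one equality fails, using the statistic
#' \eqn{\lambda = -2(\ell_0 - \ell_1)} referred to a chi-square
#' distribution with 4 degrees of freedom: under the null the two mean
#' contrasts are constrained to zero and both q and D drop out of the
#' likelihood entirely, so the full nested-parameter difference between
#' the mixture (3 means, sigma, q, D) and the single normal (mean, sigma)
#' is 4. The vignette documents the non-regularity of this testing problem
#' and the empirical null calibration supporting this reference
#' distribution.
#'
#' @param fit A `qtl_mixture_fit` from [em_fit()].
#' @param df Degrees of freedom of the chi-square reference.
#' @return A list with `stat`, `df`, `p_value`, and `converged`.
#' @export
lrt_qtl_existence <- function(fit, df = 4L) {
  stopifnot(inherits(fit, "qtl_mixture_fit"))
  if (!fit$converged)
    warning("EM did not converge; LRT p-value computed from best iterate",
            call. = FALSE)
  stat <- max(0, -2 * (fit$loglik0 - fit$loglik1))
  list(stat = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       converged = fit$converged)
}

#' Chi-square test of linkage disequilibrium between SNP and QTL
#'
#' Given a converged mixture fit, the LD null hypothesis D = 0 is tested
#' via the squared allelic correlation
#' \eqn{r^2 = \hat D^2 / (\hat p(1-\hat p)\hat q(1-\hat q))} and the
#' statistic \eqn{n r^2}, asymptotically chi-square with 1 degree of
#' freedom under the null. This test is only meaningful once QTL existence
#' is established, because D drops out of the likelihood when the genotype
#' means are equal; the multiple-testing layer enforces that ordering.
#'
#' @param fit A `qtl_mixture_fit` from [em_fit()].
#' @return A list with `stat`, `r2`, and `p_value`.
#' @export
ld_test <- function(fit) {
  stopifnot(inherits(fit, "qtl_mixture_fit"))
  p <- fit$p_hat
  q <- fit$q
  if (q <= 1e-12 || q >= 1 - 1e-12)
    stop("estimated QTL allele frequency is degenerate (q_hat = ", q, ")",
         call. = FALSE)
  r2 <- fit$D^2 / (p * (1 - p) * q * (1 - q))
  r2 <- min(r2, 1)
  stat <- fit$n_used * r2
  list(stat = stat, r2 = r2,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Both per-SNP tests from one mixture fit
#'
#' Convenience wrapper running [em_fit()] and both hypothesis tests for a
#' single SNP. Monomorphic SNPs are not testable: both p-values are
#' returned as 1 with a warning.
#'
#' @param y Numeric phenotype vector.
#' @param genotypes SNP minor-allele counts in \{0, 1, 2\} (`NA` allowed).
#' @param snp_id Identifier carried into the result.
#' @param control An [em_control()] list.
#' @return An object of class `snp_test_pair`: a list with `snp_id`,
#'   `lrt_stat`, `p_D`, `ld_stat`, `r2`, `p_L`, `n_used`, `p_hat`, `q_hat`,
#'   `D_hat`, `converged`, `monomorphic`, and the underlying `fit` (NULL
#'   when monomorphic).
#' @export
test_snp <- function(y, genotypes, snp_id = "snp", control = em_control()) {
  keep <- !is.na(y) & !is.na(genotypes)
  g <- genotypes[keep]
  mono <- length(g) == 0L || length(unique(g)) < 2L
  if (mono) {
    warning("SNP ", snp_id, " is monomorphic; tests not evaluated ",
            "(p-values set to 1)", call. = FALSE)
    return(structure(list(
      snp_id = snp_id, lrt_stat = 0, p_D = 1, ld_stat = 0, r2 = 0, p_L = 1,
      n_used = sum(keep), p_hat = NA_real_, q_hat = NA_real_,
      D_hat = NA_real_, converged = NA, monomorphic = TRUE, fit = NULL),
      class = "snp_test_pair"))
  }
  fit <- em_fit(y, genotypes, control)
  lrt <- lrt_qtl_existence(fit)
  ld <- ld_test(fit)
  structure(list(
    snp_id = snp_id, lrt_stat = lrt$stat, p_D = lrt$p_value,
    ld_stat = ld$stat, r2 = ld$r2, p_L = ld$p_value,
    n_used = fit$n_used, p_hat = fit$p_hat, q_hat = fit$q, D_hat = fit$D,
    converged = fit$converged, monomorphic = FALSE, fit = fit),
    class = "snp_test_pair")
}

#' @export
print.snp_test_pair <- function(x, ...) {
  cat("SNP", x$snp_id, "(n =", x$n_used, ")\n")
  if (x$monomorphic) {
    cat("  monomorphic: tests not evaluated\n")
    return(invisible(x))
  }
  cat(sprintf("  QTL existence: LRT = %.4g, p_D = %.4g\n", x$lrt_stat, x$p_D))
  cat(sprintf("  LD: n*r2 = %.4g (r2 = %.4g), p_L = %.4g\n",
              x$ld_stat, x$r2, x$p_L))
  invisible(x)
}
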