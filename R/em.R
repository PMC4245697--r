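#' EM control parameters
#'
#' @param tol Convergence tolerance on the relative change in the observed
#'   log-likelihood between iterations.
#' @param max_iter Maximum number of EM iterations.
#' @param n_starts Number of starts. The first start is the deterministic
#'   moment-based initialisation; additional starts jitter it (requires
#'   `seed` for reproducibility).
#' @param seed Optional integer seed used only when `n_starts > 1`.
#' @return A list of class `em_control`.
#' @export
em_control <- function(tol = 1e-8, max_iter = 1000L, n_starts = 1L,
                       seed = NULL) {
  stopifnot(tol > 0, max_iter >= 1, n_starts >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts), seed = seed),
            class = "em_control")
}

#' Observed SNP major-allele frequency
#'
#' @param genotypes Integer vector of minor-allele counts in \{0, 1, 2\};
#'   `NA` allowed (ignored).
#' @return The major-allele frequency `1 - sum(g) / (2 n)` over non-missing
#'   genotypes, with attribute `monomorphic` set to `TRUE` when the
#'   frequency is 0 or 1.
#' @export
#' @examples
#' estimate_snp_allele_freq(c(0, 1, 2, 1))  # 0.5
estimate_snp_allele_freq <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0L)
    stop("no non-missing genotypes", call. = FALSE)
  if (!all(g %in% 0:2))
    stop("genotypes must be minor-allele counts in {0, 1, 2}", call. = FALSE)
  p <- 1 - sum(g) / (2 * length(g))
  attr(p, "monomorphic") <- (p <= 0 || p >= 1)
  p
}

em_initialise <- function(y, k) {
  mu0 <- vapply(0:2, function(kk) {
    if (any(k == kk)) mean(y[k == kk]) else NA_real_
  }, numeric(1))
  mu0[is.na(mu0)] <- mean(y)
  # pooled within-genotype SD
  ss <- sum(vapply(0:2, function(kk) {
    yy <- y[k == kk]
    if (length(yy) > 1) sum((yy - mean(yy))^2) else 0
  }, numeric(1)))
  sigma0 <- sqrt(ss / length(y))
  if (!is.finite(sigma0) || sigma0 < 1e-8) sigma0 <- max(stats::sd(y), 1e-6)
  list(mu = mu0, sigma = sigma0)
}

#' Fit the LD-based QTL normal mixture by EM
#'
#' Fits the per-SNP mixture in which each phenotype is drawn from one of
#' three normal components, one per latent QTL genotype (AA, Aa, aa), with
#' a common standard deviation and mixing weights given by the conditional
#' probability of the QTL genotype given the observed SNP genotype. The SNP
#' major-allele frequency `p` is fixed at its observed estimate; the
#' genotype means, common sigma, QTL allele frequency `q` and the LD
#' coefficient `D` are estimated by maximum likelihood. The (q, D) M-step
#' uses expected two-locus haplotype counts under Hardy-Weinberg, with the
#' double-heterozygote phase resolved proportionally to the two compatible
#' haplotype-pair probabilities.
#'
#' @param y Numeric phenotype vector.
#' @param genotypes Integer vector of SNP minor-allele counts in
#'   \{0, 1, 2\}; `NA` genotypes (or phenotypes) are dropped pairwise.
#' @param control An [em_control()] list.
#' @return An object of class `qtl_mixture_fit` with elements `mu`
#'   (means for AA, Aa, aa), `sigma`, `q`, `D`, `p_hat`, `loglik1`,
#'   `loglik0` (single-normal null), `loglik_trace`, `posteriors`
#'   (n x 3 responsibilities), `n_used`, `n_iter`, `converged`.
#' @export
em_fit <- function(y, genotypes, control = em_control()) {
  stopifnot(inherits(control, "em_control"))
  if (length(y) != length(genotypes))
    stop("phenotype and genotype vectors differ in length", call. = FALSE)
  keep <- !is.na(y) & !is.na(genotypes)
  y <- as.numeric(y[keep])
  g <- as.integer(genotypes[keep])
  if (any(!is.finite(y)))
    stop("non-finite phenotype values", call. = FALSE)
  n <- length(y)
  if (n < 10L)
    stop("need at least 10 complete phenotype-genotype pairs; got ", n,
         call. = FALSE)
  if (!all(g %in% 0:2))
    stop("genotypes must be minor-allele counts in {0, 1, 2}", call. = FALSE)

  p_hat <- as.numeric(estimate_snp_allele_freq(g))
  # orient so the internal major allele has frequency >= 0.5; r^2 and the
  # LRT are invariant to this relabelling
  if (p_hat < 0.5) {
    g <- 2L - g
    p_hat <- 1 - p_hat
  }
  if (p_hat >= 1 || p_hat <= 0)
    stop("SNP is monomorphic (p_hat = ", p_hat, ")", call. = FALSE)

  k <- g  # 0 = MM (two major), 1 = Mm, 2 = mm
  init <- em_initialise(y, k)
  q0 <- p_hat
  D0 <- 0.5 * frechet_bounds(p_hat, q0)[2]

  run1 <- function(mu0, sigma0, q0, D0)
    .em_core(y, k, p_hat, mu0, sigma0, q0, D0, control$tol, control$max_iter)

  fit <- run1(init$mu, init$sigma, q0, D0)
  if (control$n_starts > 1L) {
    if (!is.null(control$seed)) set.seed(control$seed)
    for (s in seq_len(control$n_starts - 1L)) {
      mu_j <- init$mu + stats::rnorm(3, 0, init$sigma)
      frac <- stats::runif(1, 0.05, 0.95)
      alt <- run1(mu_j, init$sigma, q0, frac * frechet_bounds(p_hat, q0)[2])
      if (alt$loglik > fit$loglik) fit <- alt
    }
  }

  v0 <- mean((y - mean(y))^2)
  loglik0 <- -n / 2 * (log(2 * pi * v0) + 1)

  structure(list(
    mu = fit$mu, sigma = fit$sigma, q = fit$q, D = fit$D, p_hat = p_hat,
    loglik1 = fit$loglik, loglik0 = loglik0,
    loglik_trace = fit$loglik_trace,
    posteriors = fit$posteriors,
    n_used = n, n_iter = fit$n_iter, converged = fit$converged),
    class = "qtl_mixture_fit")
}

#' @export
print.qtl_mixture_fit <- function(x, ...) {
  cat("LD-based QTL mixture fit (n =", x$n_used, ")\n")
  cat(sprintf("  means (AA, Aa, aa): %.4g  %.4g  %.4g   sigma: %.4g\n",
              x$mu[1], x$mu[2], x$mu[3], x$sigma))
  cat(sprintf("  p_hat = %.4g  q_hat = %.4g  D_hat = %.4g\n",
              x$p_hat, x$q, x$D))
  cat(sprintf("  loglik (H1) = %.4f, loglik (H0) = %.4f, %s in %d iterations\n",
              x$loglik1, x$loglik0,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
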