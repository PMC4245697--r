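#' Simulation design for the power study
#'
#' Bundles the generating conditions for one simulation cell of the power
#' study. The defaults are the package's pinned study conditions: QTL and
#' SNP major-allele probabilities of 0.5, genotype means (1, 0, -1) for
#' (AA, Aa, aa), and LD between the causal SNP and the QTL at half its
#' upper Frechet bound (D = 0.125 at these allele frequencies). The
#' residual standard deviation is derived from the heritability:
#' \eqn{\sigma^2 = \sigma_g^2 (1 - H^2) / H^2} where \eqn{\sigma_g^2} is
#' the variance of the genotype means under the Hardy-Weinberg QTL
#' genotype distribution.
#'
#' @param n Sample size.
#' @param m Number of SNPs; SNP 1 is linked to the QTL, the remaining
#'   m - 1 SNPs are generated independently (D = 0 nulls).
#' @param h2 Heritability of the QTL, in (0, 1).
#' @param q_qtl QTL major-allele probability.
#' @param mu Genotype phenotype means, order (AA, Aa, aa).
#' @param p_snp SNP major-allele probability.
#' @param D LD between the linked SNP and the QTL; default half the upper
#'   Frechet bound for (`p_snp`, `q_qtl`).
#' @param n_reps Number of simulation replicates.
#' @param alpha Familywise error rate.
#' @param seed Root RNG seed; each replicate runs on a child seed drawn
#'   from it so cells are reproducible replicate-by-replicate.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n, m, h2, q_qtl = 0.5, mu = c(1, 0, -1),
                       p_snp = 0.5, D = NULL, n_reps = 1000L,
                       alpha = 0.05, seed = 1L) {
  stopifnot(n >= 10, m >= 1, h2 > 0, h2 < 1, length(mu) == 3,
            q_qtl > 0, q_qtl < 1, p_snp > 0, p_snp < 1,
            n_reps >= 1, alpha > 0, alpha < 1)
  b <- frechet_bounds(p_snp, q_qtl)
  if (is.null(D)) D <- 0.5 * b[2]
  if (D < b[1] || D > b[2])
    stop(sprintf("D = %g outside the Frechet bounds [%g, %g]",
                 D, b[1], b[2]), call. = FALSE)
  f <- c(q_qtl^2, 2 * q_qtl * (1 - q_qtl), (1 - q_qtl)^2)
  mu_bar <- sum(f * mu)
  sigma_g2 <- sum(f * (mu - mu_bar)^2)
  if (sigma_g2 <= 0)
    stop("genotype means are constant: genetic variance is zero",
         call. = FALSE)
  sigma <- sqrt(sigma_g2 * (1 - h2) / h2)
  structure(list(n = as.integer(n), m = as.integer(m), h2 = h2,
                 q_qtl = q_qtl, mu = mu, p_snp = p_snp, D = D,
                 sigma = sigma, sigma_g2 = sigma_g2,
                 n_reps = as.integer(n_reps), alpha = alpha,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one phenotype/genotype dataset
#'
#' Draws QTL genotypes under Hardy-Weinberg with allele probability
#' `q_qtl`; phenotypes from the genotype-specific normals with the
#' heritability-derived residual SD; the linked SNP per individual from
#' the conditional SNP-given-QTL genotype table (Bayes inversion of the
#' mixture's weights); and the remaining m - 1 SNPs independently of the
#' QTL under Hardy-Weinberg with allele probability `p_snp`. Uses the
#' current RNG stream; seed it (or use [run_power_study()]) for
#' reproducibility.
#'
#' @param config A [sim_config()].
#' @return List with `phenotypes` (length n), `genotypes` (n x m matrix of
#'   minor-allele counts, columns `snp1..snpm`), `qtl_genotypes` (1 = AA,
#'   2 = Aa, 3 = aa), `linked_snp` (column index of the linked SNP, always
#'   1), `sigma`, `sigma_g2`.
#' @export
simulate_qtl_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  m <- config$m
  f_qtl <- c(config$q_qtl^2, 2 * config$q_qtl * (1 - config$q_qtl),
             (1 - config$q_qtl)^2)
  G <- sample.int(3L, n, replace = TRUE, prob = f_qtl)
  y <- stats::rnorm(n, mean = config$mu[G], sd = config$sigma)

  geno <- matrix(NA_integer_, n, m,
                 dimnames = list(NULL, paste0("snp", seq_len(m))))
  # linked SNP: genotype index 1..3 = (MM, Mm, mm); minor-allele count is
  # index - 1
  hf <- haplotype_freqs(config$p_snp, config$q_qtl, config$D)
  cond <- snp_given_qtl(hf)$probs
  for (j in 1:3) {
    idx <- which(G == j)
    if (length(idx))
      geno[idx, 1] <- sample.int(3L, length(idx), replace = TRUE,
                                 prob = cond[j, ]) - 1L
  }
  if (m > 1) {
    f_snp <- c(config$p_snp^2, 2 * config$p_snp * (1 - config$p_snp),
               (1 - config$p_snp)^2)
    geno[, -1] <- sample.int(3L, n * (m - 1), replace = TRUE,
                             prob = f_snp) - 1L
  }
  list(phenotypes = y, genotypes = geno, qtl_genotypes = G,
       linked_snp = 1L, sigma = config$sigma, sigma_g2 = config$sigma_g2)
}

#' Per-SNP p-values for a dataset
#'
#' Runs [test_snp()] on every SNP column and returns the p-values as a
#' named vector over the graph's node identifiers (`D<i>` for QTL
#' existence, `L<i>` for LD).
#'
#' @param y Phenotype vector.
#' @param geno n x m genotype matrix of minor-allele counts.
#' @param control An [em_control()].
#' @return List with `p` (named vector length 2m), `pairs` (list of
#'   `snp_test_pair`), `n_failed` (SNPs whose fit errored; their p-values
#'   are set to 1).
#' @export
scan_pvalues <- function(y, geno, control = em_control()) {
  m <- ncol(geno)
  pairs <- vector("list", m)
  pD <- rep(1, m)
  pL <- rep(1, m)
  n_failed <- 0L
  for (i in seq_len(m)) {
    res <- tryCatch(
      suppressWarnings(test_snp(y, geno[, i],
                                snp_id = colnames(geno)[i] %||%
                                  paste0("snp", i),
                                control = control)),
      error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      pairs[[i]] <- res
      pD[i] <- res$p_D
      pL[i] <- res$p_L
    }
  }
  p <- c(pD, pL)
  names(p) <- c(paste0("D", seq_len(m)), paste0("L", seq_len(m)))
  list(p = p, pairs = pairs, n_failed = n_failed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

power_cell <- function(config, control = em_control()) {
  graph <- build_qtl_graph(config$m, config$alpha)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_reps)
  hit_gba <- logical(config$n_reps)
  hit_bon <- logical(config$n_reps)
  used <- logical(config$n_reps)
  n_failed <- 0L
  for (r in seq_len(config$n_reps)) {
    set.seed(rep_seeds[r])
    dat <- simulate_qtl_data(config)
    sc <- scan_pvalues(dat$phenotypes, dat$genotypes, control)
    n_failed <- n_failed + sc$n_failed
    gba <- sequentially_rejective(graph, sc$p)
    bon <- bonferroni_reference(sc$p, config$m, config$alpha)
    hit_gba[r] <- dat$linked_snp %in% gba$detections
    hit_bon[r] <- dat$linked_snp %in% bon$detections
    used[r] <- TRUE
  }
  n_eff <- sum(used)
  pow <- function(hit) {
    est <- mean(hit[used])
    c(power = est, mc_se = sqrt(est * (1 - est) / n_eff))
  }
  list(bonferroni = pow(hit_bon), gba = pow(hit_gba),
       n_reps = n_eff, n_failed_fits = n_failed)
}

#' Power study over a grid of simulation settings
#'
#' For every row of `grid`, simulates `n_reps` datasets, fits every SNP,
#' and computes the empirical power (probability that BOTH the QTL
#' existence and the LD hypothesis are rejected for the linked SNP) of the
#' standard Bonferroni correction at alpha/(2m) and of the graphical
#' weighted-Bonferroni procedure, together with Monte-Carlo standard
#' errors.
#'
#' @param grid Data frame with columns `h2`, `n`, `m` (one simulation cell
#'   per row).
#' @param n_reps Replicates per cell.
#' @param alpha Familywise error rate.
#' @param seed Root seed; cell i runs with seed `seed + i - 1`.
#' @param control An [em_control()].
#' @param ... Further arguments passed to [sim_config()] (e.g. `q_qtl`,
#'   `mu`, `p_snp`, `D`).
#' @return Data frame (the power table) with columns `h2`, `n`, `m`,
#'   `method` (`"bonferroni"` or `"gba"`), `power`, `mc_se`, `n_reps`,
#'   `seed`, `n_failed_fits`.
#' @export
run_power_study <- function(grid, n_reps = 1000L, alpha = 0.05, seed = 1L,
                            control = em_control(), ...) {
  stopifnot(is.data.frame(grid), all(c("h2", "n", "m") %in% names(grid)))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(n = grid$n[i], m = grid$m[i], h2 = grid$h2[i],
                      n_reps = n_reps, alpha = alpha,
                      seed = seed + i - 1L, ...)
    cell <- power_cell(cfg, control)
    out[[i]] <- data.frame(
      h2 = grid$h2[i], n = grid$n[i], m = grid$m[i],
      method = c("bonferroni", "gba"),
      power = c(cell$bonferroni["power"], cell$gba["power"]),
      mc_se = c(cell$bonferroni["mc_se"], cell$gba["mc_se"]),
      n_reps = cell$n_reps, seed = seed + i - 1L,
      n_failed_fits = cell$n_failed_fits,
      row.names = NULL)
  }
  do.call(rbind, out)
}
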