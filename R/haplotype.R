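#' Feasible range of the linkage disequilibrium coefficient
#'
#' Given major-allele probabilities `p` (SNP) and `q` (QTL), the LD
#' coefficient D is constrained to the Frechet interval
#' \eqn{\max(-pq, -(1-p)(1-q)) \le D \le \min(p(1-q), (1-p)q)}, the set of
#' values for which all four haplotype frequencies are non-negative.
#'
#' @param p SNP major-allele probability, in (0, 1).
#' @param q QTL major-allele probability, in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' frechet_bounds(0.5, 0.5)  # c(-0.25, 0.25)
frechet_bounds <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 1L, length(q) == 1L)
  c(max(-p * q, -(1 - p) * (1 - q)), min(p * (1 - q), (1 - p) * q))
}

#' Two-locus haplotype frequencies from allele frequencies and LD
#'
#' The SNP (alleles M/m, major-allele probability `p`) and the QTL
#' (alleles A/a, major-allele probability `q`) form four haplotypes
#' MA, Ma, mA, ma with frequencies
#' \deqn{p_{11} = pq + D,\quad p_{10} = p(1-q) - D,\quad
#'       p_{01} = (1-p)q - D,\quad p_{00} = (1-p)(1-q) + D.}
#'
#' @param p SNP major-allele probability, strictly inside (0, 1).
#' @param q QTL major-allele probability, strictly inside (0, 1).
#' @param D Linkage disequilibrium coefficient; must lie within
#'   [frechet_bounds()].
#' @return An object of class `haplotype_freqs`: a list with elements
#'   `p`, `q`, `D`, `p11`, `p10`, `p01`, `p00`.
#' @export
#' @examples
#' haplotype_freqs(0.5, 0.5, 0.1)
haplotype_freqs <- function(p, q, D) {
  stopifnot(length(p) == 1L, length(q) == 1L, length(D) == 1L,
            is.finite(p), is.finite(q), is.finite(D))
  if (p <= 0 || p >= 1)
    stop("SNP major-allele probability p must lie strictly in (0, 1); got ",
         p, call. = FALSE)
  if (q <= 0 || q >= 1)
    stop("QTL major-allele probability q must lie strictly in (0, 1); got ",
         q, call. = FALSE)
  b <- frechet_bounds(p, q)
  if (D < b[1] - 1e-15 || D > b[2] + 1e-15)
    stop(sprintf(
      "D = %g violates the Frechet bounds [%g, %g] for p = %g, q = %g",
      D, b[1], b[2], p, q), call. = FALSE)
  f <- c(p11 = p * q + D,
         p10 = p * (1 - q) - D,
         p01 = (1 - p) * q - D,
         p00 = (1 - p) * (1 - q) + D)
  # tiny negatives from boundary arithmetic are numerical zero
  f[f < 1e-15] <- 0
  structure(list(p = p, q = q, D = D,
                 p11 = unname(f["p11"]), p10 = unname(f["p10"]),
                 p01 = unname(f["p01"]), p00 = unname(f["p00"])),
            class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat("Two-locus haplotype frequencies (SNP x QTL)\n")
  cat(sprintf("  p = %.6g, q = %.6g, D = %.6g\n", x$p, x$q, x$D))
  cat(sprintf("  MA = %.6g  Ma = %.6g  mA = %.6g  ma = %.6g\n",
              x$p11, x$p10, x$p01, x$p00))
  invisible(x)
}

snp_genotypes <- c("MM", "Mm", "mm")
qtl_genotypes <- c("AA", "Aa", "aa")

#' Joint SNP x QTL genotype probabilities under random mating
#'
#' Assuming random union of gametes (Hardy-Weinberg at both loci jointly),
#' the 3x3 joint genotype probabilities follow from products of haplotype
#' frequencies, e.g. P(MM, AA) = p11^2 and
#' P(Mm, Aa) = 2(p11 p00 + p10 p01) (the two phases of the double
#' heterozygote).
#'
#' @param hf A `haplotype_freqs` object.
#' @return A 3x3 matrix; rows are SNP genotypes (MM, Mm, mm), columns QTL
#'   genotypes (AA, Aa, aa). Entries sum to 1.
#' @export
joint_genotype_probs <- function(hf) {
  stopifnot(inherits(hf, "haplotype_freqs"))
  with(hf, matrix(c(
    p11^2,        2 * p11 * p10,                 p10^2,
    2 * p11 * p01, 2 * (p11 * p00 + p10 * p01),  2 * p10 * p00,
    p01^2,        2 * p01 * p00,                 p00^2),
    nrow = 3, byrow = TRUE,
    dimnames = list(snp_genotypes, qtl_genotypes)))
}

cond_table <- function(probs, direction) {
  structure(list(direction = direction, probs = probs),
            class = "genotype_prob_table")
}

#' @export
print.genotype_prob_table <- function(x, ...) {
  cat("Conditional genotype probabilities:", x$direction, "\n")
  print(round(x$probs, 6))
  invisible(x)
}

#' Conditional QTL genotype probabilities given the SNP genotype
#'
#' The mixing weights of the LD-based QTL mixture model: row i gives
#' P(QTL genotype | SNP genotype i), obtained by normalising the joint
#' genotype table by the SNP genotype marginals (p^2, 2p(1-p), (1-p)^2).
#'
#' @param hf A `haplotype_freqs` object with all three SNP genotype
#'   marginals positive.
#' @return A `genotype_prob_table` with direction `"QTL_given_SNP"`; rows
#'   MM, Mm, mm; columns AA, Aa, aa; each row sums to 1.
#' @export
qtl_given_snp <- function(hf) {
  stopifnot(inherits(hf, "haplotype_freqs"))
  joint <- joint_genotype_probs(hf)
  marg <- rowSums(joint)
  if (any(marg <= 0))
    stop("SNP genotype ", snp_genotypes[which(marg <= 0)[1]],
         " has zero marginal probability (monomorphic configuration)",
         call. = FALSE)
  cond_table(sweep(joint, 1, marg, "/"), "QTL_given_SNP")
}

#' Conditional SNP genotype probabilities given the QTL genotype
#'
#' Bayes inversion of [qtl_given_snp()]: row i gives
#' P(SNP genotype | QTL genotype i), e.g. P(MM | AA) = p11^2 / q^2. Used to
#' generate linked SNPs from simulated QTL genotypes.
#'
#' @param hf A `haplotype_freqs` object with all three QTL genotype
#'   marginals positive.
#' @return A `genotype_prob_table` with direction `"SNP_given_QTL"`; rows
#'   AA, Aa, aa; columns MM, Mm, mm; each row sums to 1.
#' @export
snp_given_qtl <- function(hf) {
  stopifnot(inherits(hf, "haplotype_freqs"))
  joint <- t(joint_genotype_probs(hf))
  marg <- rowSums(joint)
  if (any(marg <= 0))
    stop("QTL genotype ", qtl_genotypes[which(marg <= 0)[1]],
         " has zero marginal probability (monomorphic configuration)",
         call. = FALSE)
  cond_table(sweep(joint, 1, marg, "/"), "SNP_given_QTL")
}
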