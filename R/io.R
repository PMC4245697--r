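#' Read a genotype matrix from TSV
#'
#' Expected layout: tab-separated with a header row; first column sample
#' IDs, remaining columns one SNP each, entries minor-allele counts in
#' \{0, 1, 2\} or missing (empty/NA).
#'
#' @param path File path.
#' @return Integer matrix (samples x SNPs) with sample IDs as row names.
#' @export
read_geno_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("genotype TSV needs a sample-ID column plus at least one SNP",
         call. = FALSE)
  ids <- as.character(df[[1]])
  g <- as.matrix(df[, -1, drop = FALSE])
  mode(g) <- "integer"
  if (any(!is.na(g) & !(g %in% 0:2)))
    stop("genotype entries must be minor-allele counts in {0, 1, 2} or NA",
         call. = FALSE)
  rownames(g) <- ids
  g
}

#' Read phenotypes from TSV
#'
#' Two tab-separated columns with a header: sample ID and a numeric trait.
#'
#' @param path File path.
#' @return Named numeric vector of phenotypes.
#' @export
read_pheno_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("phenotype file is empty", call. = FALSE)
  if (ncol(df) < 2L)
    stop("phenotype TSV needs sample-ID and trait columns", call. = FALSE)
  y <- suppressWarnings(as.numeric(df[[2]]))
  if (all(is.na(y)))
    stop("phenotype column is not numeric", call. = FALSE)
  stats::setNames(y, as.character(df[[1]]))
}

#' Read biallelic genotypes from a VCF
#'
#' Converts GT fields of biallelic records to allele counts, oriented so
#' that the counted allele is the sample minor allele (the allele with
#' frequency >= 0.5 is treated as major; ties keep the reference allele
#' major). Non-biallelic records are skipped with a warning giving the
#' count.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @return List with `genotypes` (samples x SNPs integer matrix),
#'   `snp_metadata` (data.frame: snp_id, chrom, pos), `n_skipped`.
#' @export
read_geno_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the vcfR package", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt)
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0)
    warning(n_skipped, " non-biallelic VCF record(s) skipped",
            call. = FALSE)
  if (!any(biallelic))
    stop("no biallelic records in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # ALT allele count per genotype string
  count_alt <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(v) {
      if (any(is.na(v)) || any(v == ".")) return(NA_integer_)
      sum(v == "1")
    }, integer(1))
  }
  g <- t(apply(gt, 1, count_alt))
  colnames(g) <- colnames(gt)
  # orient to minor-allele counts: flip records where ALT is the major
  # allele (frequency > 0.5)
  alt_freq <- rowMeans(g, na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  g[flip, ] <- 2L - g[flip, , drop = FALSE]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  geno <- t(g)
  colnames(geno) <- ids
  list(genotypes = geno,
       snp_metadata = data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                                 pos = fix[, "POS"],
                                 stringsAsFactors = FALSE),
       n_skipped = n_skipped)
}

#' Read and align genotype and phenotype inputs
#'
#' @param genotype_path Path to the genotype file.
#' @param phenotype_path Path to the phenotype TSV.
#' @param format `"tsv"` or `"vcf"` for the genotype file.
#' @return List with `phenotypes` (named numeric vector), `genotypes`
#'   (samples x SNPs matrix aligned to the phenotype order),
#'   `snp_metadata` (data.frame or NULL), `dropped_samples` (IDs present
#'   in only one of the two files).
#' @export
read_inputs <- function(genotype_path, phenotype_path,
                        format = c("tsv", "vcf")) {
  format <- match.arg(format)
  y <- read_pheno_tsv(phenotype_path)
  meta <- NULL
  if (format == "tsv") {
    geno <- read_geno_tsv(genotype_path)
  } else {
    v <- read_geno_vcf(genotype_path)
    geno <- v$genotypes
    meta <- v$snp_metadata
  }
  common <- intersect(names(y), rownames(geno))
  if (!length(common))
    stop("no overlapping sample IDs between genotypes and phenotypes",
         call. = FALSE)
  dropped <- union(setdiff(names(y), common), setdiff(rownames(geno), common))
  if (length(dropped))
    message("dropping ", length(dropped),
            " sample(s) absent from one input: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  list(phenotypes = y[common],
       genotypes = geno[common, , drop = FALSE],
       snp_metadata = meta, dropped_samples = dropped)
}

#' Genome scan with graphical weighted-Bonferroni correction
#'
#' Fits the LD-based QTL mixture for every SNP, computes both per-SNP
#' p-values, runs the sequentially rejective graphical procedure over all
#' 2m hypotheses, and reports raw and adjusted p-values with rejection and
#' detection flags. The LD test of a SNP whose QTL-existence hypothesis
#' was not rejected is reported as not evaluated (`NA` raw p), since LD is
#' unidentifiable when the genotype means are equal.
#'
#' @param phenotypes Named numeric vector (or plain vector aligned to
#'   genotype rows).
#' @param genotypes Samples x SNPs matrix of minor-allele counts.
#' @param alpha Familywise error rate.
#' @param control An [em_control()].
#' @param snp_metadata Optional data.frame with `snp_id`, `chrom`, `pos`.
#' @param adjusted Compute adjusted p-values (bisection per node; O(m^3
#'   log(1/tol)) overall — fine for hundreds of SNPs).
#' @return A data.frame of class `scan_report`, one row per SNP, sorted by
#'   adjusted LD p-value: `snp_id`, `chrom`, `pos`, `n_used`, `p_hat`,
#'   `q_hat`, `D_hat`, `r2`, `p_D`, `p_L`, `adj_p_D`, `adj_p_L`,
#'   `rejected_D`, `rejected_L`, `detection`.
#' @export
qtl_scan <- function(phenotypes, genotypes, alpha = 0.05,
                     control = em_control(), snp_metadata = NULL,
                     adjusted = TRUE) {
  if (!length(phenotypes))
    stop("phenotype vector is empty", call. = FALSE)
  geno <- as.matrix(genotypes)
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
  m <- ncol(geno)
  sc <- scan_pvalues(as.numeric(phenotypes), geno, control)
  mono <- vapply(sc$pairs, function(pr)
    is.null(pr) || isTRUE(pr$monomorphic), logical(1))
  if (all(mono)) {
    warning("all SNPs are monomorphic or unfittable; empty report",
            call. = FALSE)
    return(structure(data.frame(), class = c("scan_report", "data.frame")))
  }
  graph <- build_qtl_graph(m, alpha)
  res <- sequentially_rejective(graph, sc$p)
  adj <- if (adjusted) adjusted_pvalues(graph, sc$p) else
    stats::setNames(rep(NA_real_, 2 * m), graph$nodes)

  get <- function(field, default = NA_real_) vapply(sc$pairs, function(pr)
    if (is.null(pr)) default else pr[[field]], numeric(1))
  rej_D <- paste0("D", seq_len(m)) %in% res$rejected
  rej_L <- paste0("L", seq_len(m)) %in% res$rejected
  p_L_raw <- get("p_L")
  report <- data.frame(
    snp_id = colnames(geno),
    chrom = NA_character_, pos = NA_character_,
    n_used = get("n_used"),
    p_hat = get("p_hat"), q_hat = get("q_hat"), D_hat = get("D_hat"),
    r2 = get("r2"),
    p_D = get("p_D"),
    p_L = ifelse(rej_D, p_L_raw, NA_real_),
    adj_p_D = unname(adj[paste0("D", seq_len(m))]),
    adj_p_L = unname(adj[paste0("L", seq_len(m))]),
    rejected_D = rej_D, rejected_L = rej_L,
    detection = seq_len(m) %in% res$detections,
    stringsAsFactors = FALSE)
  if (!is.null(snp_metadata)) {
    i <- match(report$snp_id, snp_metadata$snp_id)
    report$chrom <- as.character(snp_metadata$chrom[i])
    report$pos <- as.character(snp_metadata$pos[i])
  }
  sort_key <- if (adjusted) report$adj_p_L else report$p_D
  report <- report[order(sort_key, report$p_D), ]
  rownames(report) <- NULL
  attr(report, "alpha") <- alpha
  attr(report, "gba_result") <- res
  class(report) <- c("scan_report", "data.frame")
  report
}

#' Write a scan report or power table as TSV
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
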