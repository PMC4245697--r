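Package: qtlgba
Title: Graphical Weighted-Bonferroni Multiplicity Correction for LD-Based QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-marker quantitative trait locus (QTL) mapping through
    linkage disequilibrium (LD) with a latent biallelic QTL, and a graphical
    weighted-Bonferroni multiple-testing procedure tailored to its two-test
    structure. Fits a three-component normal mixture per SNP by EM, with
    mixing weights structured through the SNP-to-QTL conditional genotype
    probabilities; tests QTL existence by likelihood ratio and LD by the
    n*r^2 chi-square statistic; controls the familywise error rate across
    all SNPs and both tests with a sequentially rejective two-level
    hypothesis graph that dominates the standard Bonferroni correction.
    Includes a synthetic-data generator and power-study engine, a
    closed-testing oracle for verification, adjusted p-values, and TSV/VCF
    input for genome scans.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
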