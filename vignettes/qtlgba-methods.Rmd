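---
title: "Methods: LD-based QTL mapping with graphical weighted-Bonferroni correction"
author: "qtlgba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD-based QTL mapping with graphical weighted-Bonferroni correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlgba)
```

# The problem

Single-marker association scans for quantitative traits test, SNP by SNP,
whether a latent quantitative trait locus (QTL) influences the phenotype.
In the LD-based formulation implemented here, the QTL is never observed:
each biallelic SNP (alleles M/m, major-allele probability $p$) is linked
to a putative biallelic QTL (alleles A/a, major-allele probability $q$)
through the linkage disequilibrium coefficient $D$, and the phenotype is
modelled through the QTL genotype. Declaring a QTL at a SNP requires
rejecting **two** hypotheses:

* $H^D_0$: the three QTL genotype means are equal (no QTL effect on the
  phenotype);
* $H^L_0$: $D = 0$ (the SNP is not linked to the QTL).

Both must fall for a detection, and the LD test is meaningless unless the
QTL exists, because $D$ drops out of the likelihood when the genotype
means coincide. A genome scan over $m$ SNPs therefore involves $2m$
hypotheses with a built-in logical hierarchy, which is exactly the
situation graphical weighted-Bonferroni procedures were designed for.

# The per-SNP mixture model

The two loci form four haplotypes MA, Ma, mA, ma with frequencies
$$p_{11} = pq + D,\quad p_{10} = p(1-q) - D,\quad
  p_{01} = (1-p)q - D,\quad p_{00} = (1-p)(1-q) + D,$$
non-negative exactly when $D$ lies in the Fréchet interval
$[\max(-pq, -(1-p)(1-q)),\ \min(p(1-q), (1-p)q)]$. Assuming random union
of gametes at both loci jointly (Hardy–Weinberg), products of haplotype
frequencies give the $3\times 3$ joint genotype table and from it the two
conditional tables: QTL given SNP (the mixture's weights
$\omega_{j\mid i}$) and SNP given QTL (used by the simulator,
`snp_given_qtl()`). Both are derived from joint/marginal ratios rather
than transcribed tables, which guarantees row normalisation and Bayes
consistency by construction.

Each individual's phenotype is a draw from a three-component normal
mixture indexed by its observed SNP genotype $s_i$:
$$L = \prod_{i=1}^n \sum_{j \in \{AA, Aa, aa\}}
      \omega_{j\mid s_i}(p, q, D)\,
      \phi(y_i;\ \mu_j,\ \sigma^2),$$
with a common within-genotype standard deviation $\sigma$. The SNP allele
frequency $p$ is fixed at its observed estimate $\hat p$; the free
parameters are $(\mu_{AA}, \mu_{Aa}, \mu_{aa}, \sigma, q, D)$.

## EM estimation

`em_fit()` maximises $L$ by EM. The E-step computes genotype
responsibilities $\pi_{ij} \propto \omega_{j \mid s_i} \phi(y_i; \mu_j,
\sigma)$. The M-step updates $\mu_j$ and $\sigma$ by
responsibility-weighted moments, and $(q, D)$ via expected two-locus
haplotype counts: each individual's responsibilities are distributed over
the haplotype pairs compatible with its SNP genotype and each QTL
genotype, with the double-heterozygote phase split proportionally to
$p_{11}p_{00}$ versus $p_{10}p_{01}$, and the haplotype frequencies are
re-estimated within rows under the constraint $p_{11} + p_{10} = \hat p$.
Because all of this is a standard EM on the complete data (QTL genotypes
plus phase), the observed-data log-likelihood is non-decreasing across
iterations — asserted in the test suite on a hundred seeded datasets.

Numerical choices:

* **Initialisation** — genotype means from phenotype means stratified by
  SNP genotype (MM, Mm, mm mapped to AA, Aa, aa), $\sigma$ from the
  pooled within-group SD, $q_0 = \hat p$, $D_0$ at half its upper Fréchet
  bound. One deterministic start by default; `em_control(n_starts = k,
  seed = s)` adds jittered restarts for ridge-prone data sets. The
  likelihood surface can carry long flat ridges when LD is moderate;
  the default single start occasionally terminates on one (flagged by
  `converged = FALSE` and resolved by multi-start), which we accept as
  the default-cost/robustness trade-off.
* **Convergence** — relative log-likelihood change below `tol = 1e-8`,
  at most `max_iter = 1000` iterations.
* **Constraint handling** — after each M-step, $\hat D$ is pulled
  $10^{-9}$ inside the Fréchet interval so all $\omega$ stay defined;
  $\sigma$ is floored at $10^{-10}$. The expected-count update lands
  inside the closed interval by construction, so the projection is
  active only on the exact boundary.
* **Missing data** — individuals missing the phenotype or the SNP are
  dropped per SNP (complete-case); at least 10 complete pairs are
  required. Monomorphic SNPs are not fittable: both tests report
  p-value 1 with a warning.
* **Orientation** — genotypes enter as minor-allele counts; the fit
  internally relabels so the major allele has frequency $\ge 0.5$. The
  LRT and $r^2$ are invariant to this relabelling (tested).

# The two tests

**QTL existence.** $\lambda = -2(\ell_0 - \ell_1)$, where $\ell_0$ is the
closed-form single-normal fit. We refer $\lambda$ to $\chi^2_4$: under
$H^D_0$ the two mean contrasts are pinned to zero *and* $(q, D)$ drop out
of the likelihood entirely, so the full nested-parameter difference
between the mixture (six parameters) and the single normal (two) is four.
This testing problem is non-regular — $(q, D)$ are unidentified under the
null, so no fixed $\chi^2$ is exact. We examined the empirical null
distribution of $\lambda$ (normal phenotypes independent of a
Hardy–Weinberg SNP, $n = 300$) while selecting the reference: counting
only the two mean restrictions ($\chi^2_2$) is badly anticonservative,
inflating the size several-fold and destroying familywise error control,
while the $\chi^2_4$ quantiles track the empirical ones closely, with
mild residual inflation left in the extreme tail. The suite keeps two
empirical guards: single-test size at nominal 0.05 stays below twice
nominal, and the familywise error rate of the full pipeline under the
global null ($n = 300$, $m = 5$, 2000 replicates) stays within three
binomial standard errors of $\alpha = 0.05$. `lrt_qtl_existence()`
exposes `df` for users who want a different reference.

**LD.** Once existence is established,
$r^2 = \hat D^2 / \big(\hat p(1-\hat p)\hat q(1-\hat q)\big)$ and
$n r^2$ is referred to $\chi^2_1$. $\hat p$ comes from the data, $\hat q$
and $\hat D$ from the EM fit. p-values are never floored; values are
reported to full double precision.

# The graphical procedure

`build_qtl_graph(m, alpha)` encodes the two-level scan: primary nodes
$H^D_i$ with local weights $1/m$ (fractions of $\alpha$), secondary nodes
$H^L_i$ with weight 0, an edge of weight 1 from each $H^D_i$ to its
$H^L_i$, and edges of weight $1/(m-1)$ from each $H^L_i$ back to the
other SNPs' primaries. The three regularity conditions for strong FWER
control — weights summing to at most 1, outgoing edge weights per node at
most 1, zero diagonal — are validated after **every** update, not only at
construction.

Rejecting node $h$ (`reject_and_update()`) redistributes its level and
rewires paths through it:
$$w_v \leftarrow w_v + w_h g_{hv}, \qquad
  g_{uv} \leftarrow \frac{g_{uv} + g_{uh}g_{hv}}{1 - g_{uh}g_{hu}},$$
with the quotient taken as 0 when the denominator vanishes; the
denominator re-allocates weight a node would otherwise route back to
itself through $h$. `sequentially_rejective()` repeats "reject any node
with $p \le w\alpha$" to exhaustion. When several nodes qualify we take
the smallest $p/w$ ratio first — the terminal rejection set is
order-invariant (verified exhaustively on small graphs), so this
tie-break affects only the reported order. Zero-weight nodes are never
tested; a p-value of exactly 0 is treated as the smallest positive
double, so it cannot sneak past a zero threshold. LD p-values may be
passed as `NA` ("not evaluated") and count as 1; the graph structure
already guarantees no $H^L_i$ can be rejected before $H^D_i$, because no
weight can reach it earlier.

**Adjusted p-values** are defined as the smallest familywise level at
which a node is rejected and computed by bisection to absolute tolerance
$10^{-12}$ (capped at 1). Bisection trades speed for generality; the
single-SNP closed forms (adj$(H^D) = p_D$, adj$(H^L) = \max(p_D, p_L)$)
are used as a cross-check, not as the implementation. A secondary node's
adjusted p-value can never fall below its primary's.

**Verification route.** `closed_test_oracle()` runs the underlying closed
test by brute force — every nonempty intersection hypothesis gets its
local weights by removing the complement from the initial graph, and an
elementary hypothesis is rejected iff all intersections containing it
are. The suite checks shortcut/oracle identity on thousands of random
p-vectors for $m \le 3$; the oracle is deliberately never used in the
analysis path.

**Comparator.** `bonferroni_reference()` tests all $2m$ hypotheses at
$\alpha/(2m)$. Every Bonferroni *detection* is a graph detection
(dominance, asserted on random p-vectors and full pipeline replicates).
Dominance does not hold hypothesis-by-hypothesis: Bonferroni may reject
an LD hypothesis whose primary survives — a configuration the hierarchy
deliberately rules out.

# The simulator and the power study

`simulate_qtl_data()` draws QTL genotypes under Hardy–Weinberg with
allele probability $q$; phenotypes $y_i \sim N(\mu_{G_i}, \sigma^2)$ with
$\sigma^2 = \sigma_g^2 (1 - H^2)/H^2$, where $\sigma_g^2$ is the variance
of the genotype means under the QTL genotype distribution, so the
realised heritability is exactly $H^2$; the linked SNP per individual
from the SNP-given-QTL conditional table; and $m - 1$ null SNPs
independently under Hardy–Weinberg. Generating conditions are fixed
package defaults, chosen once as a symmetric moderate-LD reference
design:

* $q = p = 0.5$ — balanced allele frequencies at both loci;
* $\mu = (1, 0, -1)$ for (AA, Aa, aa) — a purely additive QTL whose
  scale is immaterial because $\sigma$ is derived from $H^2$
  ($\sigma_g^2 = 0.5$ here);
* $D = 0.125$, half its upper Fréchet bound (true $r^2 = 0.25$) — strong
  enough LD for the model's premise without the near-deterministic
  SNP–QTL coupling of the boundary;
* $\alpha = 0.05$, 1000 replicates per cell.

All of these are arguments, not constants. The null SNPs are generated
unlinked to the QTL and to each other: the power metric concerns the
single linked SNP, and independent nulls are the standard neutral
background. A replicate counts as a success only when **both** hypotheses
for the linked SNP are rejected. One root seed spawns per-replicate child
seeds, so a cell is bit-for-bit reproducible (`run_power_study()` with
equal seeds returns identical tables).

`run_power_study()` reports both methods per cell with Monte-Carlo
standard errors. Under these conditions the graphical procedure's power
exceeds Bonferroni's in every cell, rising with $n$ and $H^2$ and falling
with $m$ — the qualitative pattern the procedure is designed to deliver.
The acceptance script (`scripts/acceptance.R`) recomputes four reference
cells, $H^2 \in \{0.1, 0.4\} \times (n, m) \in \{(100, 1), (300, 10)\}$,
at 1000 replicates.

## What the generator does and does not emulate

It emulates: a single additive biallelic QTL read through one linked SNP
in a homogeneous random-mating population, Gaussian within-genotype
phenotypes with common variance, and an unlinked polymorphic background.
It does **not** emulate: LD among the null SNPs (real SNP panels are
locally correlated, which Bonferroni-type bounds survive but which
changes effective test counts), family or population structure,
genotyping error or missingness patterns, non-normal or heteroscedastic
phenotypes, multiple or non-additive QTL. Passing power and error-rate
tests here therefore validates the procedure's logic and its behaviour
under the stated design — not robustness to those real-data features.

# Problem sizes used by the test suite

The suite favours depth over bulk at desk scale, as the package's own
choice of test design: 1000 replicates per power cell (Monte-Carlo SE
$\le 0.016$), 2000 replicates for the familywise error simulation
($n = 300$, $m = 5$), 1000 random p-vectors per graph size for the
oracle identity ($m \le 3$), 10,000 random p-vectors for detection
dominance, 200 datasets at $n = 500$ for EM parameter recovery, and a
$50$-SNP seeded end-to-end scan.

# Known limitations

* The $\chi^2_4$ reference for the existence LRT is an asymptotic
  approximation to a non-regular problem; extreme-tail p-values (far
  genome scans at tiny per-test levels) retain some inflation. A
  simulation-calibrated null would be more exact and is out of scope.
* The default single-start EM can terminate on a likelihood ridge for
  weak-signal datasets; multi-start is available but not default.
* Adjusted p-values by per-node bisection cost
  $O(\text{nodes} \times \text{rejections} \times m^2)$ per level probe;
  fine for hundreds of SNPs, not tuned for $10^5$-SNP scans (the
  rejection decision itself scales comfortably; disable adjustment with
  `adjusted = FALSE` if needed).
* Biallelic autosomal markers only; no covariates; common $\sigma$
  across genotypes by model assumption.
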