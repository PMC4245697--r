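# Shared fixtures and small independent oracles used across test files.

# A dataset from the pinned study conditions; seed makes it reproducible.
sim_fixture <- function(n, m = 1, h2 = 0.4, seed = 1, ...) {
  cfg <- sim_config(n = n, m = m, h2 = h2, seed = seed, ...)
  set.seed(seed)
  c(simulate_qtl_data(cfg), list(config = cfg))
}

# A dataset under the global null: phenotype independent of all genotypes.
null_fixture <- function(n, m = 1, seed = 1, p_snp = 0.5) {
  set.seed(seed)
  f <- c(p_snp^2, 2 * p_snp * (1 - p_snp), (1 - p_snp)^2)
  list(phenotypes = rnorm(n),
       genotypes = matrix(sample.int(3L, n * m, TRUE, prob = f) - 1L,
                          n, m, dimnames = list(NULL, paste0("snp", 1:m))))
}

# Random p-vectors over the 2m nodes, mixing clearly small, borderline and
# large values so rejection cascades of all depths occur.
random_pvec <- function(m) {
  p <- ifelse(runif(2 * m) < 0.5,
              runif(2 * m, 0, 0.1),
              runif(2 * m))
  names(p) <- c(paste0("D", 1:m), paste0("L", 1:m))
  p
}

# Independent oracle for order-invariance: explore EVERY admissible
# rejection order by branching on each currently rejectable node, and
# collect the distinct terminal rejection sets.
all_terminal_sets <- function(graph, p) {
  p <- pmax(p[graph$nodes], .Machine$double.xmin)
  results <- list()
  recurse <- function(g, rejected) {
    ok <- g$nodes[p[g$nodes] <= g$w * g$alpha]
    if (!length(ok)) {
      results[[length(results) + 1]] <<- sort(rejected)
      return(invisible())
    }
    for (h in ok) recurse(reject_and_update(g, h), c(rejected, h))
  }
  recurse(graph, character(0))
  unique(results)
}
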