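#' Two-level hypothesis graph for LD-based QTL mapping
#'
#' Builds the directed weighted graph over the 2m hypotheses of an m-SNP
#' scan: for each SNP i a primary QTL-existence hypothesis `D<i>` and a
#' secondary LD hypothesis `L<i>`. The familywise level alpha is split
#' Bonferroni-style across the primary nodes (local weight 1/m each); the
#' secondary nodes start at weight 0 and each primary node passes its full
#' weight to its own secondary node on rejection (edge weight 1). When a
#' secondary node is rejected its weight is shared equally among the other
#' SNPs' primary nodes (edge weights 1/(m-1); no such edges when m = 1).
#'
#' Local weights are stored as fractions of alpha; node `h` is tested at
#' local level `w[h] * alpha`.
#'
#' @param m Number of SNPs (>= 1).
#' @param alpha Familywise error rate, in (0, 1).
#' @return An object of class `test_graph`: list with `nodes`, `w`
#'   (named weights), `G` (named transition matrix), `alpha`.
#' @export
#' @examples
#' build_qtl_graph(3, 0.05)
build_qtl_graph <- function(m, alpha = 0.05) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m))
    stop("m must be a positive integer", call. = FALSE)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  m <- as.integer(m)
  nodes <- c(paste0("D", seq_len(m)), paste0("L", seq_len(m)))
  w <- stats::setNames(c(rep(1 / m, m), rep(0, m)), nodes)
  G <- matrix(0, 2 * m, 2 * m, dimnames = list(nodes, nodes))
  for (i in seq_len(m)) {
    G[paste0("D", i), paste0("L", i)] <- 1
    if (m > 1)
      G[paste0("L", i), paste0("D", setdiff(seq_len(m), i))] <- 1 / (m - 1)
  }
  structure(list(nodes = nodes, w = w, G = G, alpha = alpha, m = m),
            class = "test_graph")
}

#' Validate the regularity conditions of a test graph
#'
#' The procedure controls the FWER as long as (1) the local weights sum to
#' at most 1 (i.e. the local levels sum to at most alpha), (2) every row of
#' the transition matrix sums to at most 1, and (3) the diagonal is zero.
#'
#' @param graph A `test_graph`.
#' @param tol Numerical tolerance.
#' @return `TRUE` invisibly; errors describing the violated condition
#'   otherwise.
#' @export
validate_test_graph <- function(graph, tol = 1e-9) {
  stopifnot(inherits(graph, "test_graph"))
  if (any(graph$w < -tol))
    stop("negative local weight", call. = FALSE)
  if (sum(graph$w) > 1 + tol)
    stop("local weights sum to more than 1 (level exceeds alpha)",
         call. = FALSE)
  if (length(graph$nodes)) {
    if (any(graph$G < -tol) || any(graph$G > 1 + tol))
      stop("edge weight outside [0, 1]", call. = FALSE)
    if (any(rowSums(graph$G) > 1 + tol))
      stop("outgoing edge weights of a node sum to more than 1",
           call. = FALSE)
    if (any(abs(diag(graph$G)) > tol))
      stop("self-loop present (nonzero diagonal)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Remove a rejected node and redistribute its level
#'
#' One step of the sequentially rejective update: the rejected node's local
#' weight is passed along its outgoing edges, and edges are rewired so that
#' paths through the removed node are inherited,
#' \deqn{w_v \leftarrow w_v + w_h g_{hv}, \qquad
#'   g_{uv} \leftarrow \frac{g_{uv} + g_{uh} g_{hv}}{1 - g_{uh} g_{hu}},}
#' with the quotient taken as 0 when the denominator is not positive. The
#' denominator reallocates weight a node would otherwise send back to
#' itself through the removed node.
#'
#' @param graph A `test_graph`.
#' @param node Node identifier to remove.
#' @return The updated `test_graph` without `node`.
#' @export
reject_and_update <- function(graph, node) {
  stopifnot(inherits(graph, "test_graph"))
  if (!node %in% graph$nodes)
    stop("unknown node: ", node, call. = FALSE)
  keep <- setdiff(graph$nodes, node)
  G <- graph$G
  w <- graph$w
  w[keep] <- w[keep] + w[node] * G[node, keep]
  if (length(keep)) {
    gh <- G[keep, node]   # g(u, h)
    hg <- G[node, keep]   # g(h, v)
    # denominator for row u is 1 - g(u,h) g(h,u)
    denom <- 1 - gh * hg
    newG <- G[keep, keep, drop = FALSE] + outer(gh, hg)
    newG <- newG / denom                # recycles down columns: row-wise
    newG[denom <= 0 | !is.finite(newG)] <- 0
    diag(newG) <- 0
    newG[newG < 0] <- 0
    newG[newG > 1] <- 1     # guard against roundoff just above 1
  } else {
    newG <- matrix(0, 0, 0)
  }
  out <- structure(list(nodes = keep, w = w[keep], G = newG,
                        alpha = graph$alpha, m = graph$m),
                   class = "test_graph")
  validate_test_graph(out)
  out
}

node_pressure <- function(p, w) {
  # smaller is more significant; Inf when untestable (zero weight)
  ifelse(w > 0, p / w, Inf)
}

#' Sequentially rejective graphical test
#'
#' Runs the shortcut of the closed testing procedure induced by the graph:
#' repeatedly reject any node whose p-value is at most its current local
#' level `w * alpha`, redistributing its level via [reject_and_update()],
#' until no node qualifies. The final rejection set does not depend on the
#' order in which qualifying nodes are taken; ties are resolved
#' deterministically by the smallest p/w ratio.
#'
#' @param graph A `test_graph` from [build_qtl_graph()] (or compatible).
#' @param p_values Named numeric vector covering every node of `graph`.
#'   `NA` marks a p-value that was not evaluated (e.g. an LD test whose
#'   primary test was not rejected) and is treated as 1. Values of exactly
#'   0 are treated as the smallest positive double.
#' @return An object of class `gba_result`: list with `rejected`
#'   (character), `rejection_order`, `final_graph`, `detections` (integer
#'   SNP indices with both hypotheses rejected), `alpha`, `p_values`.
#' @export
sequentially_rejective <- function(graph, p_values) {
  stopifnot(inherits(graph, "test_graph"))
  p <- p_values[graph$nodes]
  if (any(!graph$nodes %in% names(p_values)))
    stop("p-value missing for node(s): ",
         paste(setdiff(graph$nodes, names(p_values)), collapse = ", "),
         call. = FALSE)
  p[is.na(p)] <- 1
  if (any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  names(p) <- graph$nodes

  g <- graph
  order_rej <- character(0)
  repeat {
    if (!length(g$nodes)) break
    pr <- node_pressure(p[g$nodes], g$w)
    ok <- p[g$nodes] <= g$w * g$alpha
    if (!any(ok)) break
    cand <- g$nodes[ok]
    h <- cand[which.min(pr[cand])]
    g <- reject_and_update(g, h)
    order_rej <- c(order_rej, h)
  }
  rejected <- order_rej
  m <- graph$m
  det <- integer(0)
  if (!is.null(m)) {
    det <- which(vapply(seq_len(m), function(i)
      all(c(paste0("D", i), paste0("L", i)) %in% rejected), logical(1)))
  }
  structure(list(rejected = rejected, rejection_order = order_rej,
                 final_graph = g, detections = det,
                 alpha = graph$alpha, p_values = p),
            class = "gba_result")
}

#' @export
print.gba_result <- function(x, ...) {
  cat("Graphical weighted-Bonferroni result (alpha =", x$alpha, ")\n")
  cat("  rejected:",
      if (length(x$rejected)) paste(x$rejected, collapse = " ") else "none",
      "\n")
  cat("  detections (both tests rejected): ",
      if (length(x$detections)) paste(x$detections, collapse = " ") else
        "none", "\n")
  invisible(x)
}

#' Adjusted p-values under the graphical procedure
#'
#' The adjusted p-value of a node is the smallest familywise level at which
#' the sequentially rejective procedure rejects it, found by bisection over
#' alpha in (0, 1] to absolute tolerance 1e-12 and capped at 1. For a
#' single SNP this reduces to the fixed-sequence closed forms
#' adj(D) = p_D and adj(L) = max(p_D, p_L); in general a secondary node's
#' adjusted p-value is never below its primary's.
#'
#' @inheritParams sequentially_rejective
#' @param tol Absolute bisection tolerance on the level.
#' @return Named numeric vector of adjusted p-values over all nodes.
#' @export
adjusted_pvalues <- function(graph, p_values, tol = 1e-12) {
  stopifnot(inherits(graph, "test_graph"))
  rejected_at <- function(alpha) {
    g <- graph
    g$alpha <- alpha
    sequentially_rejective(g, p_values)$rejected
  }
  nodes <- graph$nodes
  adj <- stats::setNames(rep(1, length(nodes)), nodes)
  at_one <- rejected_at(1)
  todo <- intersect(nodes, at_one)
  for (h in todo) {
    lo <- 0
    hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (h %in% rejected_at(mid)) hi <- mid else lo <- mid
    }
    adj[h] <- hi
  }
  adj
}

#' Closed testing oracle for the graphical procedure
#'
#' Brute-force closed testing over all nonempty subsets of hypotheses: the
#' local weights of each intersection hypothesis are obtained by removing
#' the complement from the initial graph via [reject_and_update()]; the
#' intersection is rejected when any member's p-value is at most its
#' intersection weight times alpha; an elementary hypothesis is rejected
#' overall iff every intersection containing it is rejected. Exponential in
#' the number of nodes; intended to verify [sequentially_rejective()] on
#' small graphs, not for production use.
#'
#' @inheritParams sequentially_rejective
#' @param weights Optional precomputed intersection weights from
#'   [closed_test_weights()], to amortise the subset enumeration across
#'   many p-vectors on the same graph.
#' @return Character vector of rejected node identifiers.
#' @export
closed_test_oracle <- function(graph, p_values, weights = NULL) {
  stopifnot(inherits(graph, "test_graph"))
  nodes <- graph$nodes
  if (is.null(weights)) weights <- closed_test_weights(graph)
  p <- p_values[nodes]
  p[is.na(p)] <- 1
  p <- pmax(p, .Machine$double.xmin)
  names(p) <- nodes

  rejected_all <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  for (ww in weights) {
    members <- names(ww)
    if (!any(p[members] <= ww * graph$alpha))
      rejected_all[members] <- FALSE
  }
  nodes[rejected_all]
}

#' Intersection-hypothesis weights of the closed test induced by a graph
#'
#' Enumerates every nonempty subset of the graph's nodes and computes the
#' local weights of the corresponding intersection hypothesis by removing
#' the complement from the initial graph via [reject_and_update()].
#'
#' @param graph A `test_graph` with at most 12 nodes.
#' @return A list, one element per nonempty subset, each a named numeric
#'   vector of weights over the subset's members.
#' @export
closed_test_weights <- function(graph) {
  stopifnot(inherits(graph, "test_graph"))
  nodes <- graph$nodes
  k <- length(nodes)
  if (k > 12L)
    stop("oracle enumeration limited to 12 nodes; got ", k, call. = FALSE)
  lapply(seq_len(2^k - 1), function(mask) {
    members <- nodes[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    g <- graph
    for (h in setdiff(nodes, members)) g <- reject_and_update(g, h)
    g$w[members]
  })
}

#' Standard Bonferroni reference procedure
#'
#' The comparator the graphical procedure is measured against: all 2m
#' hypotheses (QTL existence and LD for each of m SNPs) are tested at
#' alpha / (2m).
#'
#' @inheritParams sequentially_rejective
#' @param m Number of SNPs.
#' @param alpha Familywise error rate.
#' @return List with `rejected` (character vector over nodes named as in
#'   [build_qtl_graph()]), `detections` (SNP indices with both hypotheses
#'   rejected), and `threshold`.
#' @export
bonferroni_reference <- function(p_values, m, alpha = 0.05) {
  nodes <- c(paste0("D", seq_len(m)), paste0("L", seq_len(m)))
  if (any(!nodes %in% names(p_values)))
    stop("p-value missing for node(s): ",
         paste(setdiff(nodes, names(p_values)), collapse = ", "),
         call. = FALSE)
  p <- p_values[nodes]
  p[is.na(p)] <- 1
  thr <- alpha / (2 * m)
  rejected <- nodes[p <= thr]
  det <- which(vapply(seq_len(m), function(i)
    all(c(paste0("D", i), paste0("L", i)) %in% rejected), logical(1)))
  list(rejected = rejected, detections = det, threshold = thr)
}

#' @export
print.test_graph <- function(x, ...) {
  cat(format_test_graph(x), sep = "\n")
  invisible(x)
}

#' Plain-text adjacency listing of a test graph
#'
#' One line per node with its local weight (fraction of alpha) and its
#' outgoing edges, suitable for audit logs.
#'
#' @param graph A `test_graph`.
#' @return Character vector of lines.
#' @export
format_test_graph <- function(graph) {
  stopifnot(inherits(graph, "test_graph"))
  header <- sprintf("test_graph: %d nodes, alpha = %g", length(graph$nodes),
                    graph$alpha)
  lines <- vapply(graph$nodes, function(u) {
    out <- graph$G[u, ]
    out <- out[out > 0]
    edges <- if (length(out))
      paste(sprintf("%s:%.6g", names(out), out), collapse = " ")
    else "-"
    sprintf("%s w=%.6g -> %s", u, graph$w[u], edges)
  }, character(1))
  c(header, unname(lines))
}
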