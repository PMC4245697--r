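# The two-level hypothesis graph and the sequentially rejective procedure.

test_that("initial graph carries the two-level weights and edges", {
  g1 <- build_qtl_graph(1, 0.05)
  expect_equal(unname(g1$w), c(1, 0))
  expect_equal(g1$G["D1", "L1"], 1)
  expect_equal(sum(g1$G), 1)  # single edge for m = 1

  g2 <- build_qtl_graph(2, 0.05)
  expect_equal(g2$G["L1", "D2"], 1)
  expect_equal(g2$G["L2", "D1"], 1)

  g3 <- build_qtl_graph(3, 0.05)
  expect_equal(unname(g3$w[paste0("D", 1:3)]), rep(1 / 3, 3))
  expect_equal(unname(g3$w[paste0("L", 1:3)]), rep(0, 3))
  for (i in 1:3) {
    expect_equal(g3$G[paste0("D", i), paste0("L", i)], 1)
    for (j in setdiff(1:3, i))
      expect_equal(g3$G[paste0("L", i), paste0("D", j)], 1 / 2)
  }
  expect_error(build_qtl_graph(0), "positive integer")
  expect_silent(validate_test_graph(g3))
})

test_that("rejecting the primary passes its full level to its LD child (m = 1)", {
  g <- reject_and_update(build_qtl_graph(1, 0.05), "D1")
  expect_equal(unname(g$w["L1"]), 1)
  expect_error(reject_and_update(g, "nope"), "unknown node")
})

test_that("the worked m = 3 cascade frees the full level for the last SNP", {
  g <- build_qtl_graph(3, 0.05)
  for (h in c("D1", "D3", "L3", "L1")) g <- reject_and_update(g, h)
  expect_equal(unname(g$w["D2"]), 1, tolerance = 1e-12)
})

test_that("all level mass reaches the survivor whatever the removal order", {
  g0 <- build_qtl_graph(3, 0.05)
  nodes <- g0$nodes
  set.seed(1)
  # exhaustive over survivors, randomised over many removal orders each
  for (survivor in nodes) {
    others <- setdiff(nodes, survivor)
    orders <- c(list(others, rev(others)),
                replicate(10, sample(others), simplify = FALSE))
    for (ord in orders) {
      g <- g0
      for (h in ord) g <- reject_and_update(g, h)
      expect_equal(unname(g$w[survivor]), 1, tolerance = 1e-9)
    }
  }
})

test_that("regularity conditions hold after every update step", {
  set.seed(42)
  for (rep in 1:20) {
    g <- build_qtl_graph(sample(2:4, 1), 0.05)
    while (length(g$nodes) > 1) {
      h <- sample(g$nodes, 1)
      g <- reject_and_update(g, h)   # validates internally
      expect_lte(sum(g$w), 1 + 1e-9)
      if (length(g$nodes) > 0) expect_true(all(abs(diag(g$G)) < 1e-12))
      if (length(g$nodes) > 0) expect_true(all(rowSums(g$G) <= 1 + 1e-9))
    }
  }
})

test_that("no p-values below threshold means no rejections", {
  g <- build_qtl_graph(3, 0.05)
  p <- setNames(rep(1, 6), g$nodes)
  res <- sequentially_rejective(g, p)
  expect_length(res$rejected, 0)
  expect_equal(res$final_graph$w, g$w)
})

test_that("single-SNP cascade beats the Bonferroni split", {
  p <- c(D1 = 0.01, L1 = 0.03)
  res <- sequentially_rejective(build_qtl_graph(1, 0.05), p)
  expect_setequal(res$rejected, c("D1", "L1"))
  expect_equal(res$detections, 1L)
  bon <- bonferroni_reference(p, m = 1, alpha = 0.05)
  expect_equal(bon$threshold, 0.025)
  expect_equal(bon$rejected, "D1")   # 0.03 > 0.025: L1 survives Bonferroni
  expect_length(bon$detections, 0)
})

test_that("LD p-values marked unavailable are treated as 1", {
  g <- build_qtl_graph(2, 0.05)
  p <- c(D1 = 0.001, D2 = 0.5, L1 = NA, L2 = NA)
  res <- sequentially_rejective(g, p)
  expect_setequal(res$rejected, "D1")
  expect_length(res$detections, 0)
  expect_error(sequentially_rejective(g, c(D1 = -0.1, D2 = 1, L1 = 1, L2 = 1)),
               "\\[0, 1\\]")
  expect_error(sequentially_rejective(g, c(D1 = 0.1, L1 = 1)),
               "missing for node")
})

test_that("a zero-weight node is never tested, even at p = 0", {
  res <- sequentially_rejective(build_qtl_graph(1, 0.05),
                                c(D1 = 1, L1 = 0))
  expect_length(res$rejected, 0)
})

test_that("the final rejection set is invariant to the rejection order", {
  set.seed(5)
  for (m in 2:3) {
    g <- build_qtl_graph(m, 0.05)
    for (rep in 1:25) {
      p <- random_pvec(m)
      sets <- all_terminal_sets(g, p)
      expect_length(sets, 1)
      expect_equal(sort(sequentially_rejective(g, p)$rejected), sets[[1]])
    }
  }
})

test_that("rejections are monotone in the familywise level", {
  set.seed(6)
  g1 <- build_qtl_graph(3, 0.01)
  g2 <- build_qtl_graph(3, 0.05)
  g3 <- build_qtl_graph(3, 0.2)
  for (rep in 1:40) {
    p <- random_pvec(3)
    r1 <- sequentially_rejective(g1, p)$rejected
    r2 <- sequentially_rejective(g2, p)$rejected
    r3 <- sequentially_rejective(g3, p)$rejected
    expect_true(all(r1 %in% r2))
    expect_true(all(r2 %in% r3))
  }
})

test_that("an LD rejection implies its primary rejection", {
  set.seed(8)
  for (rep in 1:40) {
    m <- sample(1:3, 1)
    res <- sequentially_rejective(build_qtl_graph(m, 0.05), random_pvec(m))
    for (i in seq_len(m))
      if (paste0("L", i) %in% res$rejected)
        expect_true(paste0("D", i) %in% res$rejected)
  }
})

test_that("adjusted p-values reduce to the fixed-sequence forms for one SNP", {
  g <- build_qtl_graph(1, 0.05)
  adj <- adjusted_pvalues(g, c(D1 = 0.01, L1 = 0.03))
  expect_equal(unname(adj["D1"]), 0.01, tolerance = 1e-9)
  expect_equal(unname(adj["L1"]), 0.03, tolerance = 1e-9)
  adj <- adjusted_pvalues(g, c(D1 = 0.2, L1 = 0.001))
  expect_equal(unname(adj["D1"]), 0.2, tolerance = 1e-9)
  expect_equal(unname(adj["L1"]), 0.2, tolerance = 1e-9)  # child >= parent
})

test_that("bisection adjusted p-values agree with the closed-testing oracle", {
  set.seed(9)
  g <- build_qtl_graph(2, 0.05)
  cw <- closed_test_weights(g)
  oracle_adj <- function(p, node) {
    lo <- 0; hi <- 1
    galpha <- g
    rejected_at <- function(a) {
      galpha$alpha <- a
      node %in% closed_test_oracle(galpha, p, cw)
    }
    if (!rejected_at(1)) return(1)
    while (hi - lo > 1e-11) {
      mid <- (lo + hi) / 2
      if (rejected_at(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  for (rep in 1:5) {
    p <- random_pvec(2)
    adj <- adjusted_pvalues(g, p)
    for (node in g$nodes)
      expect_equal(unname(adj[node]), oracle_adj(p, node), tolerance = 1e-9)
  }
})

test_that("shortcut and closed-testing oracle reject identical sets", {
  set.seed(10)
  for (m in 1:3) {
    g <- build_qtl_graph(m, 0.05)
    cw <- closed_test_weights(g)
    for (rep in 1:60) {
      p <- random_pvec(m)
      expect_setequal(sequentially_rejective(g, p)$rejected,
                      closed_test_oracle(g, p, cw))
    }
    # all p above alpha: both empty
    p1 <- setNames(rep(0.9, 2 * m), g$nodes)
    expect_length(closed_test_oracle(g, p1, cw), 0)
  }
  expect_error(closed_test_weights(build_qtl_graph(7, 0.05)), "12 nodes")
})

test_that("every Bonferroni detection is also a graph detection", {
  set.seed(11)
  for (rep in 1:200) {
    m <- sample(1:4, 1)
    p <- random_pvec(m)
    gba <- sequentially_rejective(build_qtl_graph(m, 0.05), p)
    bon <- bonferroni_reference(p, m, 0.05)
    expect_true(all(bon$detections %in% gba$detections))
    # note: rejection-level dominance does NOT hold — Bonferroni may
    # reject an LD hypothesis whose primary survives, which the graph
    # structure deliberately never does; dominance is on detections
    primaries_bon <- grep("^D", bon$rejected, value = TRUE)
    expect_true(all(primaries_bon %in% gba$rejected))
  }
})

test_that("borderline p-values rejected by the cascade but not Bonferroni", {
  m <- 10
  p <- setNames(rep(0.004, 2 * m),
                c(paste0("D", 1:m), paste0("L", 1:m)))
  bon <- bonferroni_reference(p, m, 0.05)
  expect_length(bon$rejected, 0)            # 0.004 > 0.05 / 20
  gba <- sequentially_rejective(build_qtl_graph(m, 0.05), p)
  expect_length(gba$rejected, 2 * m)        # 0.004 <= 0.05 / 10, cascades
  expect_equal(gba$detections, 1:m)
})

test_that("graph export lists nodes, weights and edges", {
  txt <- format_test_graph(build_qtl_graph(2, 0.05))
  expect_length(txt, 5)
  expect_match(txt[1], "4 nodes")
  expect_match(txt[2], "^D1 w=0\\.5 -> L1:1")
})
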