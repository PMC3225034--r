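toy_dag <- function() {
  # 8-node DAG with two start and two end candidates and branching routes
  edges <- data.frame(
    source = c("s1", "s1", "a", "a", "b", "c", "s2", "s2", "d", "b"),
    target = c("a", "b", "c", "d", "c", "e1", "b", "d", "e2", "e2"))
  net <- build_network(kegg_ppi = edges)
  net <- assign_roles(net, c("s1", "s2"), c("e1", "e2"))
  expr <- data.frame(
    gene_id = c("s1", "a", "b", "c", "d", "e1", "s2", "e2"),
    p_value = c(0.01, 0.3, 0.02, 0.10, 0.6, 0.04, 0.2, 0.01),
    log_fold_change = c(2, 0.5, 1.5, 1.0, -0.2, 1.1, 0.4, 2.2))
  net <- attach_expression(net, expr)
  net$edges$reliability[net$edges$kind == "PPI"] <-
    seq(0.65, 0.95, length.out = sum(net$edges$kind == "PPI"))
  net
}

test_that("top-3 pathways on a toy DAG match brute-force enumeration", {
  net <- toy_dag()
  bg_n <- const_bg(11); bg_e <- const_bg(10)
  got <- find_trs_pathways(net, bg_n, bg_e, start = "s1", end = "e1",
                           top_k = 3)
  want <- brute_force_topk(net, "s1", "e1", max_len = 10, k = 3, bg_n, bg_e)
  expect_equal(vapply(got, function(p) paste(p$nodes, collapse = "|"),
                      character(1)),
               want)
  # scores agree with independent chain scoring
  for (p in got) {
    oracle <- score_chain(net, p$nodes, bg_n, bg_e)
    expect_equal(p$score$P, oracle$P)
    expect_equal(p$score$T, oracle$T)
    expect_equal(p$score$R, oracle$R)
    expect_equal(p$expression_score, oracle$S)
  }
})

test_that("disconnected start and end give an empty result", {
  net <- build_network(kegg_ppi = data.frame(source = c("A", "C"),
                                             target = c("B", "D")))
  net <- assign_roles(net, "A", "D")
  net <- attach_expression(net, data.frame(gene_id = "A", p_value = 0.5,
                                           log_fold_change = 0))
  expect_length(find_trs_pathways(net, const_bg(11), const_bg(10)), 0)
})

test_that("paths longer than the length cap are not returned", {
  # a single chain of 12 nodes: the only route has 11 edges
  ids <- sprintf("c%02d", 1:12)
  net <- build_network(kegg_ppi = data.frame(source = ids[-12],
                                             target = ids[-1]))
  net <- assign_roles(net, ids[1], ids[12])
  net <- attach_expression(net, data.frame(gene_id = ids, p_value = 0.01,
                                           log_fold_change = 1))
  expect_length(find_trs_pathways(net, const_bg(11), NULL, max_len = 10), 0)
  # but the same chain shortened by one node is found
  net11 <- build_network(kegg_ppi = data.frame(source = ids[-c(11, 12)],
                                               target = ids[-c(1, 12)]))
  net11 <- assign_roles(net11, ids[1], ids[11])
  net11 <- attach_expression(net11, data.frame(gene_id = ids[-12],
                                               p_value = 0.01,
                                               log_fold_change = 1))
  expect_length(find_trs_pathways(net11, const_bg(11), NULL, max_len = 10), 1)
})

test_that("unknown start or end genes are rejected", {
  net <- toy_dag()
  expect_error(find_trs_pathways(net, const_bg(11), NULL, start = "nope"),
               "not in network")
})

test_that("search equals brute force on random graphs up to 12 nodes", {
  bg_n <- const_bg(11); bg_e <- const_bg(10)
  withr::with_seed(51, {
    for (rep in 1:25) {
      net <- random_test_net(sample(6:12, 1), edge_prob = 0.25)
      k <- sample(1:5, 1)
      starts <- net$nodes$gene_id[net$nodes$is_start]
      ends <- net$nodes$gene_id[net$nodes$is_end]
      s <- sample(starts, 1); e <- sample(ends, 1)
      got <- find_trs_pathways(net, bg_n, bg_e, start = s, end = e, top_k = k)
      want <- brute_force_topk(net, s, e, max_len = 10, k = k, bg_n, bg_e)
      expect_equal(vapply(got, function(p) paste(p$nodes, collapse = "|"),
                          character(1)),
                   want)
    }
  })
})

test_that("increasing top_k preserves the order of earlier results", {
  net <- toy_dag()
  bg_n <- const_bg(11); bg_e <- const_bg(10)
  top2 <- find_trs_pathways(net, bg_n, bg_e, start = "s1", end = "e2",
                            top_k = 2)
  top5 <- find_trs_pathways(net, bg_n, bg_e, start = "s1", end = "e2",
                            top_k = 5)
  chains <- function(ps) vapply(ps, function(p) paste(p$nodes, collapse = "|"),
                                character(1))
  expect_equal(chains(top5)[seq_along(top2)], chains(top2))
})

test_that("ranking keys order pathways as documented", {
  mk <- function(nodes, T, R, S) {
    structure(list(nodes = nodes, edges = NULL,
                   score = list(T = T, R = R, P = T + R),
                   expression_score = S, p_value = NA_real_),
              class = "trs_pathway")
  }
  p1 <- mk(c("a", "x"), T = 5, R = 0, S = 1)   # high endpoints, low aggregate
  p2 <- mk(c("b", "y"), T = 3, R = 0, S = 4)   # low endpoints, high aggregate
  expect_equal(rank_pathways(list(p1, p2), by = "path_score")[[1]]$nodes[1], "a")
  expect_equal(rank_pathways(list(p1, p2), by = "expression_score")[[1]]$nodes[1], "b")
  # equal scores: lexicographic node chain
  p3 <- mk(c("a", "z"), T = 5, R = 0, S = 1)
  expect_equal(rank_pathways(list(p3, p1), by = "path_score")[[1]]$nodes,
               c("a", "x"))
})

test_that("permutation-invariant expression gives p near 1", {
  net <- toy_dag()
  net$nodes$z_score <- rep(0.3, nrow(net$nodes))  # identical for all genes
  bg_n <- const_bg(11); bg_e <- const_bg(10)
  paths <- find_trs_pathways(net, bg_n, bg_e, start = "s1", end = "e1",
                             top_k = 1)
  res <- suppressWarnings(
    pathway_pvalue(paths[[1]], net, bg_n, bg_e, n_perm = 50, seed = 3))
  expect_equal(as.numeric(res$p_value), 1)
})

test_that("scores beating every permutation are reported as a bound", {
  p <- (1 + 0) / (1000 + 1)
  attr(p, "n_perm") <- 1000
  expect_equal(format_pvalue(p), "<1.0e-03")
  expect_equal(format_pvalue(0.25, n_perm = 1000), "2.500e-01")
})

test_that("returned pathways always satisfy the structural constraints", {
  withr::with_seed(52, {
    for (rep in 1:5) {
      net <- random_test_net(12, edge_prob = 0.3)
      paths <- find_trs_pathways(net, const_bg(11), const_bg(10), top_k = 4,
                                 max_len = 6)
      for (p in paths) {
        expect_true(net$nodes$is_start[net$nodes$gene_id == p$nodes[1]])
        expect_true(net$nodes$is_end[net$nodes$gene_id ==
                                       p$nodes[length(p$nodes)]])
        expect_false(anyDuplicated(p$nodes) > 0)
        expect_lte(length(p$nodes) - 1, 6)
        expect_equal(nrow(p$edges), length(p$nodes) - 1)
      }
    }
  })
})
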