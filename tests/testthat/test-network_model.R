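test_that("an undirected PPI becomes two opposite directed edges", {
  net <- build_network(ppi_edges = data.frame(source = "A", target = "B"))
  e <- net$edges
  expect_equal(nrow(e), 2)
  expect_setequal(paste(e$source, e$target), c("A B", "B A"))
  expect_true(all(e$kind == "PPI"))
})

test_that("empty inputs give an empty network", {
  net <- build_network()
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
})

test_that("duplicate edges merge with provenance union and summed counts", {
  ppi <- data.frame(source = c("A", "A"), target = c("B", "B"),
                    provenance = c("db1", "db2"), paper_count = c(2L, 3L))
  net <- build_network(ppi_edges = ppi)
  expect_equal(nrow(net$edges), 2)  # A->B and B->A only
  ab <- net$edges[net$edges$source == "A", ]
  expect_equal(ab$provenance, "db1;db2")
  expect_equal(ab$paper_count, 5L)
})

test_that("rebuilding from duplicated inputs is idempotent", {
  ppi <- data.frame(source = c("A", "B"), target = c("B", "C"),
                    provenance = "db1", paper_count = 1L)
  pd <- data.frame(source = "C", target = "A")
  once <- build_network(ppi, pd)
  twice <- build_network(rbind(ppi, ppi), rbind(pd, pd))
  expect_equal(twice$edges, once$edges)
})

test_that("a directed-only PPI source does not spawn a reverse edge", {
  net <- build_network(kegg_ppi = data.frame(source = "A", target = "B"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$source, "A")
})

test_that("self-loops are tolerated and collapse to one edge", {
  net <- build_network(ppi_edges = data.frame(source = "A", target = "A"))
  expect_equal(nrow(net$edges), 1)
})

test_that("role assignment sets independent start and end flags", {
  net <- build_network(ppi_edges = data.frame(source = "A", target = "B"))
  net <- assign_roles(net, "A", "B")
  expect_true(net$nodes$is_start[net$nodes$gene_id == "A"])
  expect_true(net$nodes$is_end[net$nodes$gene_id == "B"])
  both <- assign_roles(net, c("A"), c("A", "B"))
  expect_true(both$nodes$is_start[both$nodes$gene_id == "A"] &&
                both$nodes$is_end[both$nodes$gene_id == "A"])
  expect_message(assign_roles(net, c("A", "ZZZ"), "B"), "absent")
  expect_error(assign_roles(net, character(0), "B"), "non-empty")
})

test_that("localization filter removes only backward PPI edges", {
  ppi <- data.frame(source = "M", target = "E")      # membrane -> extracellular
  pd <- data.frame(source = "M", target = "E")
  net <- build_network(ppi_edges = ppi, pd_edges = pd)
  net <- attach_localization(net, data.frame(
    gene_id = c("M", "E"), localization = c("plasma_membrane", "extracellular")))
  filtered <- suppressMessages(localization_filter(net))
  kinds <- filtered$edges$kind
  # of the two directed PPI copies only E->M survives; the PD edge is exempt
  expect_equal(sum(kinds == "PPI"), 1)
  expect_equal(filtered$edges$source[kinds == "PPI"], "E")
  expect_equal(sum(kinds == "PD"), 1)
})

test_that("multi-localized nodes keep an edge if any pair is ordered", {
  net <- build_network(kegg_ppi = data.frame(source = "A", target = "B"))
  net <- attach_localization(net, data.frame(
    gene_id = c("A", "A", "B"),
    localization = c("cytoplasm", "nucleus", "nucleus")))
  filtered <- localization_filter(net)
  expect_equal(nrow(filtered$edges), 1)  # (cytoplasm, nucleus) is ordered
})

test_that("unannotated and other-only nodes are unconstrained", {
  net <- build_network(kegg_ppi = data.frame(source = c("A", "B"),
                                             target = c("B", "C")))
  net <- attach_localization(net, data.frame(
    gene_id = c("A", "B"), localization = c("nucleus", "other")))
  filtered <- localization_filter(net)
  expect_equal(nrow(filtered$edges), 2)
})

test_that("localization filter is idempotent and never adds edges", {
  withr::with_seed(11, {
    net <- random_test_net(10, edge_prob = 0.4)
  })
  net <- attach_localization(net, data.frame(
    gene_id = net$nodes$gene_id,
    localization = sample(c("extracellular", "plasma_membrane", "cytoplasm",
                            "nucleus", "other"),
                          nrow(net$nodes), replace = TRUE)))
  f1 <- suppressMessages(localization_filter(net))
  f2 <- suppressMessages(localization_filter(f1))
  expect_lte(nrow(f1$edges), nrow(net$edges))
  expect_equal(f2$edges, f1$edges)
  expect_true(all(f1$edges$kind != "PPI" |
                    paste(f1$edges$source, f1$edges$target) %in%
                      paste(net$edges$source, net$edges$target)))
})

test_that("DEG calls use a strict cutoff and unmatched genes stay neutral", {
  net <- build_network(ppi_edges = data.frame(source = c("A", "B"),
                                              target = c("B", "C")))
  tab <- data.frame(gene_id = c("A", "B"), p_value = c(0.04, 0.05),
                    log_fold_change = c(1.2, -0.3))
  net <- attach_expression(net, tab)
  n <- net$nodes
  expect_true(n$is_deg[n$gene_id == "A"])
  expect_false(n$is_deg[n$gene_id == "B"])   # p = 0.05 is not < 0.05
  expect_equal(n$z_score[n$gene_id == "C"], 0)
  expect_false(n$is_deg[n$gene_id == "C"])
  expect_equal(n$z_score[n$gene_id == "A"], qnorm(1 - 0.04))
})

test_that("out-of-range p-values are rejected by gene name", {
  net <- build_network(ppi_edges = data.frame(source = "A", target = "B"))
  expect_error(
    attach_expression(net, data.frame(gene_id = "A", p_value = 1.2,
                                      log_fold_change = 0)),
    "A")
})

test_that("DEG count equals the count of p-values under the cutoff", {
  withr::with_seed(7, {
    net <- random_test_net(20, edge_prob = 0.2)
  })
  cutoff <- 0.1
  tab <- data.frame(gene_id = net$nodes$gene_id,
                    p_value = net$nodes$p_value,
                    log_fold_change = net$nodes$log_fold_change)
  net2 <- attach_expression(net, tab, deg_cutoff = cutoff)
  expect_equal(sum(net2$nodes$is_deg), sum(tab$p_value < cutoff))
})
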