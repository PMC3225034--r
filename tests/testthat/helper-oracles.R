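# Shared fixtures and independent oracles for the test suite.

# Identity background: corrected score == raw aggregate. Removes Monte-Carlo
# noise from tests that target search/score mechanics rather than the
# background estimation itself.
const_bg <- function(k_max, mu = 0, sigma = 1, kind = "node_z") {
  tab <- data.frame(k = seq_len(k_max), mu = mu, sigma = sigma,
                    mu_smoothed = mu, sigma_smoothed = sigma)
  attr(tab, "kind") <- kind
  attr(tab, "n_samples") <- NA_integer_
  attr(tab, "window") <- 1L
  class(tab) <- c("background_table", "data.frame")
  tab
}

# Brute-force enumeration of all simple start -> end node chains with at
# most max_len edges over the PPI edges (pathways relay signal along
# protein chains). Plain recursive DFS over an adjacency list built
# directly from the edge table -- independent of the beam search.
enumerate_chains <- function(net, start, end, max_len) {
  ppi <- net$edges[net$edges$kind == "PPI", , drop = FALSE]
  adj <- split(ppi$target, ppi$source)
  adj <- lapply(adj, function(x) sort(unique(x)))
  out <- list()
  walk <- function(chain) {
    tail <- chain[length(chain)]
    if (length(chain) >= 2 && tail == end) out[[length(out) + 1L]] <<- chain
    if (length(chain) > max_len) return(invisible(NULL))
    for (nb in adj[[tail]]) {
      if (!(nb %in% chain)) walk(c(chain, nb))
    }
    invisible(NULL)
  }
  walk(start)
  out
}

# Score a node chain with the package's scoring operations, choosing the
# PPI edge wherever both a PPI and a PD edge connect a consecutive pair.
score_chain <- function(net, chain, bg_nodes, bg_edges) {
  z <- stats::setNames(net$nodes$z_score, net$nodes$gene_id)
  te <- path_expression_score(unname(z[chain]), bg_nodes)
  rels <- numeric(0)
  for (i in seq_len(length(chain) - 1L)) {
    hit <- net$edges[net$edges$source == chain[i] &
                       net$edges$target == chain[i + 1L], , drop = FALSE]
    hit <- hit[order(hit$kind != "PPI"), , drop = FALSE][1, ]
    if (hit$kind == "PPI" && !is.na(hit$reliability)) {
      rels <- c(rels, hit$reliability)
    }
  }
  R <- path_reliability_score(rels, bg_edges)
  list(T = te$T, S = te$S, R = R, P = te$T + R)
}

# Exhaustive top-k start -> end pathways by brute force.
brute_force_topk <- function(net, start, end, max_len, k, bg_nodes, bg_edges) {
  chains <- enumerate_chains(net, start, end, max_len)
  if (length(chains) == 0) return(character(0))
  P <- vapply(chains, function(ch) score_chain(net, ch, bg_nodes, bg_edges)$P,
              numeric(1))
  key <- vapply(chains, paste, character(1), collapse = "|")
  key[order(-P, key)][seq_len(min(k, length(key)))]
}

# Random small directed network with expression, roles and reliabilities;
# used for search-oracle and property tests.
random_test_net <- function(n_nodes, edge_prob = 0.25, pd_frac = 0.15,
                            n_starts = 2, n_ends = 2) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  all_pairs <- expand.grid(source = ids, target = ids,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
  picked <- all_pairs[stats::runif(nrow(all_pairs)) < edge_prob, , drop = FALSE]
  if (nrow(picked) < 2) picked <- all_pairs[1:2, ]
  is_pd <- stats::runif(nrow(picked)) < pd_frac
  net <- build_network(kegg_ppi = picked[!is_pd, , drop = FALSE],
                       kegg_pd = if (any(is_pd)) picked[is_pd, , drop = FALSE] else NULL)
  net <- assign_roles(net, sample(ids, n_starts), sample(ids, n_ends))
  expr <- data.frame(gene_id = ids,
                     p_value = stats::runif(n_nodes),
                     log_fold_change = stats::rnorm(n_nodes))
  net <- attach_expression(net, expr)
  is_ppi <- net$edges$kind == "PPI"
  net$edges$reliability[is_ppi] <- stats::runif(sum(is_ppi), 0.6, 1)
  net
}

# Hand-traceable seven-node fixture for the network-growth algorithm.
# Directed PPI chains S1 -> A -> T1 and S2 -> B -> T2 (plus T2 -> C), and a
# protein-DNA edge from the transcription factor T1 to the induced start
# protein S2. Expected growth from S1, traced by hand through the expansion:
#   seed = S1->A->T1; queue = [T1]
#   poll T1: edge T1->S2 (PD): S2 is a DEG -> add S2 + edge;
#     S2 is a start, a DEG, positively regulated -> pull S2's top pathway
#     S2->B->T2 (adds S2,B,T2 and both edges), enqueue T2
#   poll T2: edge T2->C: C is not a DEG and not in the network -> skip
#   queue empty; C stays out.
toy_growth_fixture <- function() {
  ppi <- data.frame(source = c("S1", "A", "S2", "B", "T2"),
                    target = c("A", "T1", "B", "T2", "C"),
                    stringsAsFactors = FALSE)
  pd <- data.frame(source = "T1", target = "S2", stringsAsFactors = FALSE)
  net <- build_network(kegg_ppi = ppi, pd_edges = pd)
  net <- assign_roles(net, c("S1", "S2"), c("T1", "T2"))
  expr <- data.frame(
    gene_id = c("S1", "A", "T1", "S2", "B", "T2", "C"),
    p_value = c(0.01, 0.2, 0.3, 0.01, 0.04, 0.02, 0.5),
    log_fold_change = c(1, 0.3, 0.2, 1.2, 0.8, 0.9, -0.1))
  net <- attach_expression(net, expr)
  is_ppi <- net$edges$kind == "PPI"
  net$edges$reliability[is_ppi] <- 0.9
  net
}

# Localization-order admissibility of one edge, restated independently of
# the implementation (used by the constraint-enforcement property test).
loc_ok <- function(src_loc, tgt_loc) {
  rank <- c(extracellular = 0, plasma_membrane = 1, cytoplasm = 2, nucleus = 3)
  ru <- rank[intersect(strsplit(src_loc, ";")[[1]], names(rank))]
  rv <- rank[intersect(strsplit(tgt_loc, ";")[[1]], names(rank))]
  length(ru) == 0 || length(rv) == 0 || min(ru) <= max(rv)
}
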