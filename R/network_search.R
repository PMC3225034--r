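# TRS Network growth: queue-based expansion of a seed pathway along
# transcription-factor -> target edges to newly induced start proteins,
# capturing transcription-mediated cross-talk between pathways.

edge_key <- function(s, t, kind) paste(s, t, kind, sep = "\r")

#' Grow a TRS Network from a seed TRS Pathway
#'
#' Executes the queue-based expansion: (1) seed with the top-ranked pathway
#' of `start_gene` (when unset, the start of the globally highest-scoring
#' pathway); (2) enqueue the seed's end node; then, while the queue is
#' non-empty, poll an end node and walk its outgoing edges in sorted
#' (target, kind) order. A target that is a DEG or already in the network is
#' added together with the edge. An added target that is a start gene, a
#' DEG, and positively regulated (log fold change > 0) pulls in its
#' top-ranked significant pathways (permutation p <=
#' `significance_cutoff`, capped at `max_pathways_per_start` by score;
#' pathways without a p-value pass) and their end nodes are enqueued. An
#' added target that is an end gene and a DEG is enqueued. Each node is
#' polled at most once and each start gene pulls its pathways at most once,
#' so the expansion always terminates.
#'
#' @param net an `omics_network` with expression attached.
#' @param pathways list of scored `trs_pathway` objects (all starts).
#' @param start_gene seed start gene id, or NULL to infer it from the
#'   highest-scoring pathway.
#' @param significance_cutoff pathway permutation-p cutoff for pulled
#'   pathways (default 0.05).
#' @param max_pathways_per_start cap on pulled pathways per start gene
#'   (default 3).
#' @param p_filter apply the significance cutoff (default TRUE). Disabled
#'   in permutation reruns, where nested permutation p-values would be
#'   quadratic in the permutation count.
#' @return A `trs_network`: list with `nodes`, `edges`, `member_pathways`,
#'   `seed_gene`, and unset score slots (see [score_trs_network()]).
#' @export
grow_trs_network <- function(net, pathways, start_gene = NULL,
                             significance_cutoff = 0.05,
                             max_pathways_per_start = 3L,
                             p_filter = TRUE) {
  if (length(pathways) == 0) stop("empty pathway list")
  stopifnot(inherits(net, "omics_network"))
  starts_of <- vapply(pathways, function(p) p$nodes[1], character(1))
  P_of <- vapply(pathways, function(p) p$score$P, numeric(1))
  pv_of <- vapply(pathways, function(p) as.numeric(p$p_value), numeric(1))
  chains <- vapply(pathways, function(p) paste(p$nodes, collapse = "|"), character(1))

  top_of <- function(gene, apply_filter, cap) {
    sel <- starts_of == gene
    if (apply_filter) sel <- sel & (is.na(pv_of) | pv_of <= significance_cutoff)
    idx <- which(sel)
    idx[order(-P_of[idx], chains[idx])][seq_len(min(cap, length(idx)))]
  }

  if (is.null(start_gene)) {
    best <- order(-P_of, chains)[1]
    start_gene <- starts_of[best]
    seed_idx <- best
  } else {
    cand <- top_of(start_gene, apply_filter = FALSE, cap = 1L)
    if (length(cand) == 0) {
      stop(sprintf("no pathway starts at '%s'", start_gene))
    }
    seed_idx <- cand
  }
  seed <- pathways[[seed_idx]]

  is_deg <- node_field(net, "is_deg")
  lfc <- node_field(net, "log_fold_change")
  is_start <- node_field(net, "is_start")
  is_end <- node_field(net, "is_end")

  e <- net$edges[order(net$edges$source, net$edges$target, net$edges$kind), ,
                 drop = FALSE]
  out_rows <- split(seq_len(nrow(e)), e$source)

  nodes <- character(0)
  ekeys <- character(0)
  members <- list()
  member_chains <- character(0)

  add_pathway <- function(pw) {
    chain <- paste(pw$nodes, collapse = "|")
    if (chain %in% member_chains) return(invisible(NULL))
    nodes <<- union(nodes, pw$nodes)
    ekeys <<- union(ekeys, edge_key(pw$edges$source, pw$edges$target, pw$edges$kind))
    members[[length(members) + 1L]] <<- pw
    member_chains <<- c(member_chains, chain)
    invisible(NULL)
  }

  add_pathway(seed)
  queue <- seed$nodes[length(seed$nodes)]
  processed <- character(0)
  pulled <- character(0)

  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% processed) next
    processed <- c(processed, v)
    for (i in out_rows[[v]] %||% integer(0)) {
      t_i <- e$target[i]
      if (isTRUE(is_deg[t_i]) || t_i %in% nodes) {
        nodes <- union(nodes, t_i)
        ekeys <- union(ekeys, edge_key(e$source[i], t_i, e$kind[i]))
        if (isTRUE(is_start[t_i]) && isTRUE(is_deg[t_i]) &&
            isTRUE(lfc[t_i] > 0) && !(t_i %in% pulled)) {
          pulled <- c(pulled, t_i)
          for (j in top_of(t_i, apply_filter = p_filter,
                           cap = max_pathways_per_start)) {
            pw <- pathways[[j]]
            add_pathway(pw)
            pw_end <- pw$nodes[length(pw$nodes)]
            if (!(pw_end %in% processed) && !(pw_end %in% queue)) {
              queue <- c(queue, pw_end)
            }
          }
        }
        if (isTRUE(is_end[t_i]) && isTRUE(is_deg[t_i]) &&
            !(t_i %in% processed) && !(t_i %in% queue)) {
          queue <- c(queue, t_i)
        }
      }
    }
  }

  keys_all <- edge_key(net$edges$source, net$edges$target, net$edges$kind)
  structure(list(
    nodes = sort(nodes),
    edges = net$edges[keys_all %in% ekeys, , drop = FALSE],
    member_pathways = members,
    seed_gene = start_gene,
    components = NULL, SF = NA_real_, p_value = NA_real_
  ), class = "trs_network")
}

#' Score a TRS Network
#'
#' Computes the three components of the composite score: S, the
#' background-corrected aggregate z over all network nodes; the sum of the
#' member pathways' path scores; and the edge count. Nodes and edges outside
#' every member pathway contribute to S and the edge count only.
#'
#' @param g a `trs_network`.
#' @param net the `omics_network` the network was grown from.
#' @param bg_nodes node-z `background_table` covering the network's node
#'   count.
#' @return The network with `components` (S, P_sum, n_edges) and `SF` set.
#' @export
score_trs_network <- function(g, net, bg_nodes) {
  stopifnot(inherits(g, "trs_network"))
  if (length(g$nodes) == 0) stop("cannot score an empty network")
  z <- node_field(net, "z_score")[g$nodes]
  S <- corrected_score(aggregate_z(z), length(z), bg_nodes)
  P_sum <- sum(vapply(g$member_pathways, function(p) p$score$P, numeric(1)))
  n_edges <- nrow(g$edges)
  g$components <- list(S = S, P_sum = P_sum, n_edges = n_edges)
  g$SF <- network_score(S, P_sum, n_edges)
  g
}

#' @export
print.trs_network <- function(x, ...) {
  cat(sprintf("TRS Network (seed %s): %d nodes, %d edges, %d member pathways\n",
              x$seed_gene, length(x$nodes), nrow(x$edges),
              length(x$member_pathways)))
  if (!is.null(x$components)) {
    cat(sprintf("  SF = %.3f  (S = %.3f, sum P = %.3f, |E| = %d)%s\n",
                x$SF, x$components$S, x$components$P_sum, x$components$n_edges,
                if (is.na(x$p_value)) "" else sprintf("  p = %s",
                                                      format_pvalue(x$p_value))))
  }
  invisible(x)
}

#' Run the full TRS Network search on a network
#'
#' Convenience pipeline: finds top pathways for all start/end role pairs,
#' grows the TRS Network from `start_gene` (or the inferred start), and
#' scores it. Member-pathway permutation p-values are not computed here
#' (`p_filter = FALSE` in the growth step); use [pathway_pvalue()] and
#' [grow_trs_network()] directly for a significance-filtered growth.
#'
#' @inheritParams find_trs_pathways
#' @inheritParams grow_trs_network
#' @return A scored `trs_network` (or NULL when no pathway exists).
#' @export
run_network_analysis <- function(net, bg_nodes, bg_edges = NULL,
                                 start_gene = NULL, max_len = 10L,
                                 top_k = 5L, overgen = 20L,
                                 max_frontier = 4000L,
                                 significance_cutoff = 0.05,
                                 max_pathways_per_start = 3L) {
  paths <- find_trs_pathways(net, bg_nodes, bg_edges,
                             max_len = max_len, top_k = top_k,
                             overgen = overgen, max_frontier = max_frontier)
  if (length(paths) == 0) return(NULL)
  g <- grow_trs_network(net, paths, start_gene = start_gene,
                        significance_cutoff = significance_cutoff,
                        max_pathways_per_start = max_pathways_per_start,
                        p_filter = FALSE)
  score_trs_network(g, net, bg_nodes)
}

#' Permutation p-value of a TRS Network
#'
#' Permutes the expression annotation of the network's genes and reruns the
#' identical pathway search plus network growth, comparing the permuted
#' composite scores SF against the observed one. The observed SF is
#' recomputed through the same pipeline so observation and permutations are
#' exchangeable under the null.
#'
#' @param g a `trs_network` (its seed gene fixes the search start; pass
#'   `infer_start = TRUE` to re-infer the start per permutation, matching a
#'   run where no start gene was given).
#' @inheritParams run_network_analysis
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param infer_start logical; re-infer the start gene per permutation.
#' @return The network with `p_value` set.
#' @export
network_pvalue <- function(g, net, bg_nodes, bg_edges = NULL,
                           n_perm = 1000L, seed = NULL,
                           max_len = 10L, top_k = 5L, overgen = 20L,
                           max_frontier = 4000L,
                           significance_cutoff = 0.05,
                           max_pathways_per_start = 3L,
                           infer_start = FALSE) {
  if (n_perm < 100) warning("fewer than 100 permutations gives a coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  start_gene <- if (infer_start) NULL else g$seed_gene
  run_sf <- function(network) {
    res <- tryCatch(
      run_network_analysis(network, bg_nodes, bg_edges,
                           start_gene = start_gene, max_len = max_len,
                           top_k = top_k, overgen = overgen,
                           max_frontier = max_frontier,
                           significance_cutoff = significance_cutoff,
                           max_pathways_per_start = max_pathways_per_start),
      error = function(e) NULL)
    if (is.null(res)) -Inf else res$SF
  }
  obs <- run_sf(net)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    if (run_sf(permute_expression(net)) >= obs) n_ge <- n_ge + 1L
  }
  g$p_value <- (1 + n_ge) / (n_perm + 1)
  attr(g$p_value, "n_perm") <- n_perm
  g
}
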