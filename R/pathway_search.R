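# Candidate TRS Pathway search.
#
# The path score P(N,E) is non-additive in the edges (the background
# correction depends on path length), so no edge weight exists for which a
# shortest-path algorithm is exact. Candidate generation therefore runs a
# k-best label-correcting search stratified by path length on a non-negative
# additive surrogate weight
#     w(u -> v) = (z_max - z_v) + (1 - r_uv)
# (r_uv = 1 for PD edges), keeping the best `top_k * overgen` partial paths
# per (node, depth) plus a global per-depth frontier cap, and then rescores
# every completed candidate exactly with P(N,E).

# Compressed adjacency over the network's PPI edges. Pathway search relays
# the signal along protein chains only: protein-DNA edges act through
# transcription, which is the between-pathway mechanism handled by the
# network-growth step (which iterates raw edges of both kinds).
make_search_graph <- function(net) {
  gene_ids <- net$nodes$gene_id
  n <- length(gene_ids)
  e <- net$edges[net$edges$kind == "PPI", , drop = FALSE]
  src <- match(e$source, gene_ids)
  tgt <- match(e$target, gene_ids)
  o <- order(src, tgt)
  src <- src[o]; tgt <- tgt[o]
  is_ppi <- (e$kind == "PPI")[o]
  rel <- e$reliability[o]
  rel_known <- is_ppi & !is.na(rel)
  counts <- tabulate(src, nbins = n)
  ptr2 <- cumsum(counts)
  ptr1 <- ptr2 - counts + 1L
  list(
    gene_ids = gene_ids, n = n,
    ptr1 = ptr1, ptr2 = ptr2, counts = counts,
    flat_nb = tgt,
    flat_rel = ifelse(rel_known, rel, 0),
    flat_nppi = as.integer(rel_known),
    flat_base = ifelse(rel_known, 1 - rel, 0),
    is_start = stats::setNames(net$nodes$is_start, gene_ids),
    is_end = stats::setNames(net$nodes$is_end, gene_ids)
  )
}

# Core beam search. starts/ends: integer node indices. Returns per-depth
# candidate blocks (path matrix, aggregates) for exact rescoring.
beam_search <- function(sg, z, starts, ends, max_len, beam, max_frontier) {
  if (length(starts) == 0 || length(ends) == 0) return(list())
  z_max <- max(z)
  flat_w <- sg$flat_base + (z_max - z[sg$flat_nb])
  is_end_idx <- logical(sg$n); is_end_idx[ends] <- TRUE

  P <- matrix(starts, ncol = 1)
  tails <- starts
  zsum <- z[starts]
  relsum <- numeric(length(starts))
  nppi <- integer(length(starts))
  w <- numeric(length(starts))
  out <- vector("list", max_len)

  for (d in seq_len(max_len)) {
    cnt <- sg$counts[tails]
    keep_par <- cnt > 0L
    if (!any(keep_par)) break
    m <- sum(keep_par)
    Pp <- P[keep_par, , drop = FALSE]
    long_i <- rep.int(seq_len(m), cnt[keep_par])
    slot <- sequence(cnt[keep_par]) + rep.int(sg$ptr1[tails[keep_par]] - 1L,
                                              cnt[keep_par])
    nb <- sg$flat_nb[slot]
    dup <- nb == Pp[long_i, 1]
    if (ncol(Pp) > 1) {
      for (col in 2:ncol(Pp)) dup <- dup | (nb == Pp[long_i, col])
    }
    ok <- !dup
    if (!any(ok)) break
    long_i <- long_i[ok]; slot <- slot[ok]; nb <- nb[ok]
    zsum_p <- zsum[keep_par]; relsum_p <- relsum[keep_par]
    nppi_p <- nppi[keep_par]; w_p <- w[keep_par]
    P <- cbind(Pp[long_i, , drop = FALSE], nb)
    tails <- nb
    zsum <- zsum_p[long_i] + z[nb]
    relsum <- relsum_p[long_i] + sg$flat_rel[slot]
    nppi <- nppi_p[long_i] + sg$flat_nppi[slot]
    w <- w_p[long_i] + flat_w[slot]

    done <- is_end_idx[tails]
    if (any(done)) {
      out[[d]] <- list(P = P[done, , drop = FALSE], zsum = zsum[done],
                       relsum = relsum[done], nppi = nppi[done])
    }
    if (d == max_len) break

    # per-(node, depth) beam, then global frontier cap, both by surrogate w
    o <- order(tails, w)
    grp_rank <- stats::ave(seq_along(o), tails[o], FUN = seq_along)
    keep_idx <- o[grp_rank <= beam]
    if (length(keep_idx) > max_frontier) {
      keep_idx <- keep_idx[order(w[keep_idx])[seq_len(max_frontier)]]
    }
    P <- P[keep_idx, , drop = FALSE]
    tails <- tails[keep_idx]; zsum <- zsum[keep_idx]
    relsum <- relsum[keep_idx]; nppi <- nppi[keep_idx]; w <- w[keep_idx]
  }
  out[!vapply(out, is.null, logical(1))]
}

# Exact rescoring of candidate blocks with P(N,E). Returns a data.frame:
# start, end, chain, n_nodes, S, T, R, P plus a list-column-free matrix ref.
rescore_candidates <- function(blocks, sg, z, bg_nodes, bg_edges) {
  res <- lapply(blocks, function(b) {
    n <- ncol(b$P)
    S <- (b$zsum / sqrt(n) - bg_nodes$mu_smoothed[n]) / bg_nodes$sigma_smoothed[n]
    Tscore <- S + z[b$P[, 1]] + z[b$P[, n]]
    if (is.null(bg_edges)) {
      R <- numeric(length(S))
    } else {
      R <- ifelse(b$nppi > 0,
                  (b$relsum / sqrt(pmax(b$nppi, 1)) -
                     bg_edges$mu_smoothed[pmax(b$nppi, 1)]) /
                    bg_edges$sigma_smoothed[pmax(b$nppi, 1)],
                  0)
    }
    chain <- sg$gene_ids[b$P[, 1]]
    if (n > 1) for (col in 2:n) chain <- paste(chain, sg$gene_ids[b$P[, col]], sep = "|")
    data.frame(start = sg$gene_ids[b$P[, 1]], end = sg$gene_ids[b$P[, n]],
               chain = chain, n_nodes = n, S = S, T = Tscore, R = R,
               P = Tscore + R, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Find top-scoring TRS Pathways
#'
#' Enumerates candidate simple paths from start-role to end-role genes
#' along PPI edges (at most `max_len` edges; protein-DNA edges act through
#' transcription and belong to the network-growth layer), scores each with
#' \eqn{P(N,E) = T(N) + R(E)}, and returns the `top_k` best. Candidates are
#' generated by a length-stratified k-best search on an additive surrogate
#' weight and rescored exactly; on small graphs the candidate set is
#' effectively exhaustive. With `start`/`end` unset, all start/end role
#' pairs are searched and `top_k` is enforced per (start, end) pair before
#' pooling.
#'
#' @param net an `omics_network`, already localization- and
#'   reliability-filtered, with expression attached.
#' @param bg_nodes node-z `background_table` covering sizes up to
#'   `max_len + 1`.
#' @param bg_edges edge-reliability `background_table` covering sizes up to
#'   `max_len`, or NULL to score R(E) = 0 throughout.
#' @param start,end a gene id, or NULL for all genes with the role.
#' @param max_len maximum number of edges per path (default 10).
#' @param top_k number of pathways to keep (per pair in all-pairs mode).
#' @param overgen candidate over-generation factor: the per-(node, depth)
#'   beam keeps `top_k * overgen` partial paths (default 20).
#' @param max_frontier global cap on partial paths per depth (default 4000).
#' @return A list of `trs_pathway` objects sorted by decreasing path score
#'   (ties broken lexicographically on the node chain).
#' @export
find_trs_pathways <- function(net, bg_nodes, bg_edges = NULL,
                              start = NULL, end = NULL,
                              max_len = 10L, top_k = 5L, overgen = 20L,
                              max_frontier = 4000L) {
  sg <- make_search_graph(net)
  z <- stats::setNames(net$nodes$z_score, net$nodes$gene_id)
  resolve <- function(ids, role) {
    if (is.null(ids)) return(which(role))
    idx <- match(ids, sg$gene_ids)
    if (anyNA(idx)) stop(sprintf("gene(s) not in network: %s",
                                 paste(ids[is.na(idx)], collapse = ", ")))
    idx
  }
  starts <- resolve(start, sg$is_start)
  ends <- resolve(end, sg$is_end)
  if (length(starts) == 0 || length(ends) == 0) return(list())
  if (nrow(bg_nodes) < max_len + 1) {
    stop("node background table must cover sizes up to max_len + 1")
  }
  blocks <- beam_search(sg, z, starts, ends, max_len,
                        beam = top_k * overgen, max_frontier = max_frontier)
  if (length(blocks) == 0) return(list())
  cand <- rescore_candidates(blocks, z, sg = sg, bg_nodes = bg_nodes,
                             bg_edges = bg_edges)
  per_pair <- is.null(start) || is.null(end) ||
    length(starts) > 1 || length(ends) > 1
  o <- order(cand$start, cand$end, -cand$P, cand$chain)
  cand <- cand[o, , drop = FALSE]
  if (per_pair) {
    rank_in_pair <- stats::ave(seq_len(nrow(cand)),
                               paste(cand$start, cand$end, sep = "\r"),
                               FUN = seq_along)
    cand <- cand[rank_in_pair <= top_k, , drop = FALSE]
  }
  cand <- cand[order(-cand$P, cand$chain), , drop = FALSE]
  if (!per_pair) cand <- utils::head(cand, top_k)
  lapply(seq_len(nrow(cand)), function(i) {
    as_trs_pathway(cand[i, ], net)
  })
}

as_trs_pathway <- function(row, net) {
  nodes <- strsplit(row$chain, "|", fixed = TRUE)[[1]]
  edges <- path_edges(net, nodes)
  structure(list(
    nodes = nodes, edges = edges,
    score = list(T = row$T, R = row$R, P = row$P),
    expression_score = row$S,
    p_value = NA_real_
  ), class = "trs_pathway")
}

# Edge rows along a node chain; PPI preferred where both kinds exist.
path_edges <- function(net, nodes) {
  e <- net$edges
  out <- lapply(seq_len(length(nodes) - 1L), function(i) {
    hit <- e[e$source == nodes[i] & e$target == nodes[i + 1L], , drop = FALSE]
    if (nrow(hit) == 0) stop(sprintf("no edge %s -> %s", nodes[i], nodes[i + 1L]))
    hit[order(hit$kind != "PPI"), , drop = FALSE][1, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.trs_pathway <- function(x, ...) {
  cat(sprintf("TRS Pathway (%d nodes): %s\n  T = %.3f  R = %.3f  P = %.3f  S = %.3f%s\n",
              length(x$nodes), paste(x$nodes, collapse = " -> "),
              x$score$T, x$score$R, x$score$P, x$expression_score,
              if (is.na(x$p_value)) "" else sprintf("  p = %s", format_pvalue(x$p_value))))
  invisible(x)
}

#' Rank TRS Pathways by path score or expression score
#'
#' Stable descending sort by the chosen key; ties are broken
#' lexicographically on the node chain.
#'
#' @param paths list of `trs_pathway` objects.
#' @param by `"path_score"` (P) or `"expression_score"` (the aggregate-only
#'   corrected score S).
#' @return The reordered list.
#' @export
rank_pathways <- function(paths, by = c("path_score", "expression_score")) {
  by <- match.arg(by)
  key <- vapply(paths, function(p) {
    if (by == "path_score") p$score$P else p$expression_score
  }, numeric(1))
  chains <- vapply(paths, function(p) paste(p$nodes, collapse = "|"), character(1))
  paths[order(-key, chains)]
}

#' Convert a pathway list to a data.frame
#'
#' @param paths list of `trs_pathway` objects.
#' @return data.frame with columns rank, start, end, node_chain, T, R, P,
#'   expression_score, p_value.
#' @export
pathways_table <- function(paths) {
  if (length(paths) == 0) {
    return(data.frame(rank = integer(), start = character(), end = character(),
                      node_chain = character(), T = numeric(), R = numeric(),
                      P = numeric(), expression_score = numeric(),
                      p_value = numeric()))
  }
  data.frame(
    rank = seq_along(paths),
    start = vapply(paths, function(p) p$nodes[1], character(1)),
    end = vapply(paths, function(p) p$nodes[length(p$nodes)], character(1)),
    node_chain = vapply(paths, function(p) paste(p$nodes, collapse = "|"), character(1)),
    T = vapply(paths, function(p) p$score$T, numeric(1)),
    R = vapply(paths, function(p) p$score$R, numeric(1)),
    P = vapply(paths, function(p) p$score$P, numeric(1)),
    expression_score = vapply(paths, function(p) p$expression_score, numeric(1)),
    p_value = vapply(paths, function(p) p$p_value, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Best path score between fixed start/end indices for a given z assignment;
# -Inf when no admissible path exists. Shared by the permutation tests.
best_path_score <- function(sg, z, start_idx, end_idx, bg_nodes, bg_edges,
                            max_len, beam, max_frontier) {
  blocks <- beam_search(sg, z, start_idx, end_idx, max_len, beam, max_frontier)
  if (length(blocks) == 0) return(-Inf)
  cand <- rescore_candidates(blocks, sg = sg, z = z, bg_nodes = bg_nodes,
                             bg_edges = bg_edges)
  max(cand$P)
}

# Permute the expression annotation (p, logFC, z, DEG flag) across genes.
permute_expression <- function(net, perm = NULL) {
  n <- nrow(net$nodes)
  if (is.null(perm)) perm <- sample.int(n)
  for (col in c("p_value", "log_fold_change", "z_score", "is_deg")) {
    net$nodes[[col]] <- net$nodes[[col]][perm]
  }
  net
}

#' Permutation p-value of a TRS Pathway
#'
#' Randomly permutes the expression annotation of the network's genes,
#' repeats the identical path search between the pathway's start and end,
#' and counts permutations whose best path score reaches the observed best.
#' The estimate is \eqn{p = (1 + \#\{perm \ge obs\}) / (n_{perm} + 1)}.
#' The observed score is recomputed with the same search configuration so
#' observation and permutations are exchangeable under the null.
#'
#' @param path a `trs_pathway`.
#' @inheritParams find_trs_pathways
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return The pathway with `p_value` set.
#' @export
pathway_pvalue <- function(path, net, bg_nodes, bg_edges = NULL,
                           n_perm = 1000L, seed = NULL,
                           max_len = 10L, top_k = 5L, overgen = 20L,
                           max_frontier = 4000L) {
  if (n_perm < 100) warning("fewer than 100 permutations gives a coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  sg <- make_search_graph(net)
  z <- net$nodes$z_score
  s_idx <- match(path$nodes[1], sg$gene_ids)
  e_idx <- match(path$nodes[length(path$nodes)], sg$gene_ids)
  beam <- top_k * overgen
  obs <- best_path_score(sg, z, s_idx, e_idx, bg_nodes, bg_edges,
                         max_len, beam, max_frontier)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    zp <- z[sample.int(length(z))]
    sc <- best_path_score(sg, zp, s_idx, e_idx, bg_nodes, bg_edges,
                          max_len, beam, max_frontier)
    if (sc >= obs) n_ge <- n_ge + 1L
  }
  path$p_value <- (1 + n_ge) / (n_perm + 1)
  attr(path$p_value, "n_perm") <- n_perm
  path
}

#' Format a permutation p-value for reporting
#'
#' Scores exceeding every permutation are reported as an upper bound
#' (`"<1.0e-03"` at 1000 permutations).
#'
#' @param p numeric p-value from a permutation test.
#' @param n_perm number of permutations used.
#' @return A character scalar.
#' @export
format_pvalue <- function(p, n_perm = attr(p, "n_perm") %||% NULL) {
  if (!is.null(n_perm) && isTRUE(p <= 1 / (n_perm + 1))) {
    sprintf("<%.1e", 1 / n_perm)
  } else {
    sprintf("%.3e", as.numeric(p))
  }
}
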