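# Baseline construction and overlap statistics against reference pathways.

#' Build the D2D baseline subnetwork
#'
#' The DEG-to-DEG (D2D) network links differentially expressed genes through
#' their direct PPIs: its nodes are the DEGs present in the network and its
#' edges are all PPI edges with both endpoints in the DEG set.
#'
#' @param net an `omics_network`.
#' @param degs character vector of DEG gene ids (ids absent from the network
#'   are ignored with a message).
#' @return A `trs_network`-shaped subnetwork with no member pathways.
#' @export
build_d2d_network <- function(net, degs) {
  stopifnot(inherits(net, "omics_network"))
  absent <- setdiff(degs, net$nodes$gene_id)
  if (length(absent) > 0) {
    message(sprintf("%d DEG id(s) absent from the network ignored", length(absent)))
  }
  degs <- intersect(degs, net$nodes$gene_id)
  e <- net$edges
  keep <- e$kind == "PPI" & e$source %in% degs & e$target %in% degs
  structure(list(
    nodes = sort(degs),
    edges = e[keep, , drop = FALSE],
    member_pathways = list(),
    seed_gene = NA_character_,
    components = NULL, SF = NA_real_, p_value = NA_real_
  ), class = "trs_network")
}

# One-sided Fisher exact p (hypergeometric upper tail) for drawing >= a
# reference members in a sample of size n_sub from a universe containing
# n_ref reference members.
hyper_upper_tail <- function(overlap, n_sub, n_ref, n_universe) {
  stats::phyper(overlap - 1, n_ref, n_universe - n_ref, n_sub,
                lower.tail = FALSE)
}

#' Overlap significance of a subnetwork against a reference pathway
#'
#' One-sided Fisher exact test (hypergeometric upper tail) on the 2x2 table
#' of membership in the subnetwork crossed with membership in the reference,
#' over a stated universe. The p-value is also returned as its negative
#' natural logarithm.
#'
#' @param sub a `trs_network` (or any list with `nodes` and `edges`).
#' @param reference list with `nodes` (character) and optionally `edges`
#'   (data.frame `source`, `target` and optionally `kind`).
#' @param universe list with `nodes` and (for edge-level tests) `edges`
#'   drawn from the filtered omics network; [network_universe()] builds it.
#' @param level `"node"` or `"edge"`.
#' @param directed logical; at the edge level, match directed
#'   (source, target) pairs (default TRUE) or unordered pairs (for reference
#'   pathways without direction).
#' @return An `overlap_result`: list with the 2x2 `contingency` counts
#'   (a, b, c, d), `p_value` and `neg_log_p`.
#' @export
overlap_significance <- function(sub, reference, universe,
                                 level = c("node", "edge"),
                                 directed = TRUE) {
  level <- match.arg(level)
  ekey <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    if (directed) paste(df$source, df$target, sep = "\r")
    else paste(pmin(df$source, df$target), pmax(df$source, df$target), sep = "\r")
  }
  if (level == "node") {
    uni <- unique(universe$nodes)
    s <- intersect(unique(sub$nodes), uni)
    r <- intersect(unique(reference$nodes), uni)
  } else {
    uni <- unique(ekey(universe$edges))
    s <- intersect(unique(ekey(sub$edges)), uni)
    r <- intersect(unique(ekey(reference$edges)), uni)
  }
  if (length(uni) == 0) stop("empty universe")
  a <- length(intersect(s, r))
  b <- length(s) - a
  c_ <- length(r) - a
  d <- length(uni) - a - b - c_
  p <- hyper_upper_tail(a, length(s), length(r), length(uni))
  structure(list(level = level,
                 contingency = c(a = a, b = b, c = c_, d = d),
                 p_value = p, neg_log_p = -log(p)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("%s overlap: a=%d b=%d c=%d d=%d  p = %.3e  -ln p = %.3f\n",
              x$level, x$contingency["a"], x$contingency["b"],
              x$contingency["c"], x$contingency["d"], x$p_value, x$neg_log_p))
  invisible(x)
}

#' Node and edge universe of a network
#'
#' @param net an `omics_network`.
#' @return list with `nodes` and `edges` suitable as the `universe` of
#'   [overlap_significance()].
#' @export
network_universe <- function(net) {
  list(nodes = net$nodes$gene_id, edges = net$edges[, c("source", "target")])
}

#' Annotate network edges matching kinase-substrate pairs
#'
#' Phosphorylation drives signal transduction; edges matching a known
#' (kinase, substrate) pair are flagged `kinase_reaction = TRUE`, which
#' makes the reported networks easier to interpret.
#'
#' @param g a `trs_network` or `omics_network`.
#' @param pairs data.frame with columns `kinase`, `substrate`.
#' @return `g` with a logical `kinase_reaction` edge column.
#' @export
annotate_kinase_reactions <- function(g, pairs) {
  e <- g$edges
  if (is.null(pairs) || nrow(pairs) == 0) {
    e$kinase_reaction <- rep(FALSE, nrow(e))
  } else {
    e$kinase_reaction <- paste(e$source, e$target, sep = "\r") %in%
      paste(pairs$kinase, pairs$substrate, sep = "\r")
  }
  g$edges <- e
  g
}
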