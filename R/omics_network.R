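#' @keywords internal
"_PACKAGE"

# Subcellular compartments ordered along the direction of signal flow.
LOC_RANK <- c(extracellular = 0L, plasma_membrane = 1L, cytoplasm = 2L, nucleus = 3L)
LOC_LEVELS <- c(names(LOC_RANK), "other")

new_omics_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "omics_network")
}

empty_nodes <- function(gene_ids = character()) {
  data.frame(
    gene_id = gene_ids,
    localizations = rep("", length(gene_ids)),
    is_start = logical(length(gene_ids)),
    is_end = logical(length(gene_ids)),
    p_value = rep(NA_real_, length(gene_ids)),
    log_fold_change = rep(NA_real_, length(gene_ids)),
    z_score = numeric(length(gene_ids)),
    is_deg = logical(length(gene_ids)),
    stringsAsFactors = FALSE
  )
}

empty_edges <- function() {
  data.frame(
    source = character(), target = character(), kind = character(),
    provenance = character(), paper_count = integer(),
    pd_sign = character(), reliability = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Build a directed omics network from interaction edge lists
#'
#' Integrates protein-protein (PPI) and protein-DNA (PD) interactions into a
#' single directed graph. Undirected PPIs are transformed into two directed
#' edges with opposite directions; directed PPI lists (e.g. extracted from
#' curated pathway maps) and PD edges keep their stated direction. Duplicate
#' edges across sources are merged by the (source, target, kind) key with
#' provenance union and per-source literature counts summed.
#'
#' @param ppi_edges data.frame of undirected PPI pairs with columns `source`,
#'   `target` and optionally `provenance` (database tag) and `paper_count`.
#' @param pd_edges data.frame of directed protein-DNA edges (transcription
#'   factor -> target gene); optional columns `provenance`, `paper_count`,
#'   `pd_sign` (one of `"positive"`, `"negative"`, `"unknown"`).
#' @param kegg_ppi data.frame of directed PPI edges; a direction present only
#'   here does not spawn a reverse edge.
#' @param kegg_pd data.frame of directed PD edges.
#' @return An `omics_network`: a list with data.frames `nodes` and `edges`.
#' @examples
#' net <- build_network(data.frame(source = "A", target = "B"))
#' net$edges[, c("source", "target", "kind")]
#' @export
build_network <- function(ppi_edges = NULL, pd_edges = NULL,
                          kegg_ppi = NULL, kegg_pd = NULL) {
  norm <- function(df, default_prov) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    stopifnot(all(c("source", "target") %in% names(df)))
    df$source <- as.character(df$source)
    df$target <- as.character(df$target)
    if (is.null(df$provenance)) df$provenance <- default_prov
    if (is.null(df$paper_count)) df$paper_count <- 0L
    if (is.null(df$pd_sign)) df$pd_sign <- NA_character_
    bad <- is.na(df$source) | is.na(df$target) | df$source == "" | df$target == ""
    if (any(bad)) {
      warning(sprintf("skipping %d edge(s) with unresolvable identifiers", sum(bad)))
      df <- df[!bad, , drop = FALSE]
    }
    df[c("source", "target", "provenance", "paper_count", "pd_sign")]
  }

  parts <- list()
  ppi <- norm(ppi_edges, "ppi")
  if (!is.null(ppi)) {
    fwd <- ppi; rev <- ppi
    rev$source <- ppi$target; rev$target <- ppi$source
    both <- rbind(fwd, rev)
    both$kind <- "PPI"
    parts <- c(parts, list(both))
  }
  kppi <- norm(kegg_ppi, "kegg")
  if (!is.null(kppi)) { kppi$kind <- "PPI"; parts <- c(parts, list(kppi)) }
  for (x in list(norm(pd_edges, "pd"), norm(kegg_pd, "kegg"))) {
    if (!is.null(x)) { x$kind <- "PD"; parts <- c(parts, list(x)) }
  }

  if (length(parts) == 0) {
    return(new_omics_network(empty_nodes(), empty_edges()))
  }
  all <- do.call(rbind, parts)

  # collapse duplicates within a provenance tag (max count), then merge tags
  key_tag <- paste(all$source, all$target, all$kind, all$provenance, sep = "\r")
  o <- order(key_tag, -all$paper_count)
  all <- all[o, , drop = FALSE][!duplicated(key_tag[o]), , drop = FALSE]

  key <- paste(all$source, all$target, all$kind, sep = "\r")
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  merged <- all[first, , drop = FALSE]
  merged$provenance <- vapply(
    split(all$provenance, grp),
    function(p) paste(sort(unique(p)), collapse = ";"), character(1)
  )[as.character(seq_len(sum(first)))]
  merged$paper_count <- as.integer(vapply(split(all$paper_count, grp), sum,
                                          numeric(1))[as.character(seq_len(sum(first)))])
  sign_merge <- vapply(split(all$pd_sign, grp), function(s) {
    s <- unique(s[!is.na(s)])
    if (length(s) == 1) s else if (length(s) == 0) NA_character_ else "unknown"
  }, character(1))[as.character(seq_len(sum(first)))]
  merged$pd_sign <- ifelse(merged$kind == "PD", sign_merge, NA_character_)
  merged$reliability <- NA_real_

  edges <- merged[order(merged$source, merged$target, merged$kind),
                  c("source", "target", "kind", "provenance", "paper_count",
                    "pd_sign", "reliability")]
  rownames(edges) <- NULL
  nodes <- empty_nodes(sort(unique(c(edges$source, edges$target))))
  new_omics_network(nodes, edges)
}

#' Assign start and end roles to network genes
#'
#' Start proteins are ligands or transmembrane proteins from which a signal
#' can originate; end proteins are transcription factors or proteins with a
#' clearly defined terminal role. A gene may carry both roles. Identifiers
#' absent from the network are ignored with a message.
#'
#' @param net an `omics_network`.
#' @param start_ids,end_ids character vectors of gene identifiers.
#' @return The network with `is_start` / `is_end` set on its nodes.
#' @export
assign_roles <- function(net, start_ids, end_ids) {
  stopifnot(inherits(net, "omics_network"))
  if (length(start_ids) == 0 || length(end_ids) == 0) {
    stop("start and end role sets must both be non-empty")
  }
  absent <- setdiff(c(start_ids, end_ids), net$nodes$gene_id)
  if (length(absent) > 0) {
    message(sprintf("%d role gene(s) absent from the network: %s",
                    length(absent), paste(utils::head(absent, 5), collapse = ", ")))
  }
  net$nodes$is_start <- net$nodes$gene_id %in% start_ids
  net$nodes$is_end <- net$nodes$gene_id %in% end_ids
  net
}

#' Attach subcellular localization annotation
#'
#' @param net an `omics_network`.
#' @param loc_table data.frame with columns `gene_id`, `localization`
#'   (one row per gene/compartment; values among
#'   extracellular, plasma_membrane, cytoplasm, nucleus, other).
#' @return The network with the `localizations` node column filled
#'   (semicolon-delimited; empty string means unannotated).
#' @export
attach_localization <- function(net, loc_table) {
  stopifnot(inherits(net, "omics_network"))
  loc_table <- as.data.frame(loc_table, stringsAsFactors = FALSE)
  bad <- !(loc_table$localization %in% LOC_LEVELS)
  if (any(bad)) {
    message(sprintf("%d localization value(s) outside the known vocabulary kept as 'other'",
                    sum(bad)))
    loc_table$localization[bad] <- "other"
  }
  collapsed <- vapply(split(loc_table$localization, loc_table$gene_id),
                      function(l) paste(sort(unique(l)), collapse = ";"),
                      character(1))
  idx <- match(net$nodes$gene_id, names(collapsed))
  hit <- !is.na(idx)
  net$nodes$localizations[hit] <- unname(collapsed[idx[hit]])
  net
}

loc_ranks <- function(loc_string) {
  if (is.na(loc_string) || loc_string == "") return(integer(0))
  l <- strsplit(loc_string, ";", fixed = TRUE)[[1]]
  unname(LOC_RANK[l[l %in% names(LOC_RANK)]])
}

#' Remove PPI edges that run against the direction of signal flow
#'
#' Signals travel from the extracellular region to the plasma membrane, then
#' the cytoplasm, then the nucleus. A PPI edge u -> v is kept if and only if
#' some pair of compartments (one of u's, one of v's) is non-decreasing in
#' that order, or if either endpoint has no ranked compartment annotation
#' (unannotated and "other"-only nodes are unconstrained). PD edges act at
#' the nucleus by definition and are never removed.
#'
#' @param net an `omics_network` with localizations attached.
#' @return A new filtered network; the input is unmodified.
#' @export
localization_filter <- function(net) {
  stopifnot(inherits(net, "omics_network"))
  e <- net$edges
  if (nrow(e) == 0) return(net)
  rank_list <- lapply(net$nodes$localizations, loc_ranks)
  names(rank_list) <- net$nodes$gene_id
  min_rank <- vapply(rank_list, function(r) if (length(r)) min(r) else -1L, numeric(1))
  max_rank <- vapply(rank_list, function(r) if (length(r)) max(r) else 99L, numeric(1))
  is_ppi <- e$kind == "PPI"
  keep <- !is_ppi | (min_rank[e$source] <= max_rank[e$target])
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("localization filter removed %d PPI edge(s)", dropped))
  }
  net$edges <- e[keep, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

#' Attach differential-expression results to network genes
#'
#' Each matched gene receives its p-value, log fold change, the z-score
#' \eqn{z_i = \Phi^{-1}(1 - p_i)}, and a DEG flag (`p_value < deg_cutoff`,
#' strict). Genes without a measurement keep z = 0 and are not DEGs, a
#' neutral contribution to aggregate scores.
#'
#' @param net an `omics_network`.
#' @param table data.frame with columns `gene_id`, `p_value`,
#'   `log_fold_change` (or `logFC`).
#' @param deg_cutoff DEG p-value cutoff (default 0.05).
#' @return The annotated network.
#' @export
attach_expression <- function(net, table, deg_cutoff = 0.05) {
  stopifnot(inherits(net, "omics_network"), deg_cutoff >= 0, deg_cutoff <= 1)
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(table$log_fold_change) && !is.null(table$logFC)) {
    table$log_fold_change <- table$logFC
  }
  bad <- !is.na(table$p_value) & (table$p_value < 0 | table$p_value > 1)
  if (any(bad)) {
    stop(sprintf("p-value outside [0,1] for gene(s): %s",
                 paste(utils::head(table$gene_id[bad], 5), collapse = ", ")))
  }
  if (anyDuplicated(table$gene_id)) {
    warning("duplicated gene ids in expression table; keeping first occurrence")
    table <- table[!duplicated(table$gene_id), , drop = FALSE]
  }
  idx <- match(net$nodes$gene_id, table$gene_id)
  hit <- !is.na(idx) & !is.na(table$p_value[idx])
  net$nodes$p_value[hit] <- table$p_value[idx[hit]]
  net$nodes$log_fold_change[hit] <- table$log_fold_change[idx[hit]]
  net$nodes$z_score <- ifelse(hit, z_from_p(net$nodes$p_value), 0)
  net$nodes$is_deg <- hit & net$nodes$p_value < deg_cutoff
  net
}

#' @export
print.omics_network <- function(x, ...) {
  kinds <- table(factor(x$edges$kind, levels = c("PPI", "PD")))
  cat(sprintf(
    "omics network: %d nodes, %d edges (%d PPI, %d PD); %d start, %d end, %d DEG\n",
    nrow(x$nodes), nrow(x$edges), kinds[["PPI"]], kinds[["PD"]],
    sum(x$nodes$is_start), sum(x$nodes$is_end), sum(x$nodes$is_deg)))
  invisible(x)
}

#' Set PPI edge reliabilities directly
#'
#' Joins a table of per-pair reliabilities onto the network's PPI edges
#' (matched in either direction, as PPIs are undirected pairs). Useful when
#' reliabilities come from an external source rather than
#' [estimate_mean_reliability()].
#'
#' @param net an `omics_network`.
#' @param reliability_table data.frame with columns `source`, `target`,
#'   `mean_reliability`.
#' @return The network with the edge `reliability` column filled.
#' @export
set_edge_reliability <- function(net, reliability_table) {
  stopifnot(inherits(net, "omics_network"))
  r <- as.data.frame(reliability_table, stringsAsFactors = FALSE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- r$mean_reliability[match(key(net$edges$source, net$edges$target),
                                  key(r$source, r$target))]
  is_ppi <- net$edges$kind == "PPI"
  net$edges$reliability[is_ppi] <- lut[is_ppi]
  net
}

node_field <- function(net, field) {
  stats::setNames(net$nodes[[field]], net$nodes$gene_id)
}
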