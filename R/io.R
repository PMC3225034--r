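# Readers and writers for the plain-text interchange formats: TSV edge
# lists, SIF, role lists, localization and expression tables, GMT gene
# sets, and GraphML export through igraph.

read_tsv_checked <- function(path, required) {
  nf <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(nf) == 0) stop(sprintf("%s: empty file", path))
  bad <- which(nf != nf[1])
  if (length(bad) > 0) {
    stop(sprintf("%s: malformed line %d (expected %d fields, found %d)",
                 path, bad[1], nf[1], nf[bad[1]]))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Read an interaction edge list
#'
#' TSV with header columns `source`, `target` and optionally `kind`,
#' `provenance`, `paper_count`, `pd_sign`.
#'
#' @param path file path.
#' @return data.frame of edges.
#' @export
read_edge_list <- function(path) {
  read_tsv_checked(path, c("source", "target"))
}

#' Read a SIF interaction file
#'
#' Simple interaction format: `source <relation> target [target2 ...]` per
#' line, whitespace-delimited.
#'
#' @param path file path.
#' @return data.frame with columns `source`, `target`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    stop(sprintf("%s: malformed line %d (fewer than 3 fields)", path, short[1]))
  }
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(source = p[1], target = p[-(1:2)], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a localization table
#'
#' TSV with columns `gene_id`, `localization`; multiple rows per gene.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_localizations <- function(path) {
  read_tsv_checked(path, c("gene_id", "localization"))
}

#' Read a role gene list (one gene id per line)
#'
#' @param path file path.
#' @return character vector.
#' @export
read_roles <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}

#' Read a differential-expression table
#'
#' TSV with columns `gene_id`, `p_value` and `log_fold_change` (or `logFC`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "p_value"))
  if (is.null(df$log_fold_change) && !is.null(df$logFC)) {
    df$log_fold_change <- df$logFC
  }
  df
}

#' Read gene sets in GMT format
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' Write scenario data as interchange files
#'
#' Emits `ppi.tsv`, `pd.tsv`, `localization.tsv`, `starts.txt`, `ends.txt`,
#' `reliability.tsv` and `expression.tsv` into a directory, in the same
#' formats the readers consume.
#'
#' @param scd a `trs_scenario_data`.
#' @param dir output directory (created if needed).
#' @param expression optional expression table (default: generated from the
#'   scenario).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scd, dir, expression = NULL) {
  stopifnot(inherits(scd, "trs_scenario_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(scd$ppi_pairs, "ppi.tsv")
  wt(scd$pd_edges, "pd.tsv")
  wt(scd$localizations, "localization.tsv")
  wt(scd$reliability, "reliability.tsv")
  writeLines(scd$starts, file.path(dir, "starts.txt"))
  writeLines(scd$ends, file.path(dir, "ends.txt"))
  if (is.null(expression)) expression <- generate_expression(scd)
  wt(expression, "expression.tsv")
  invisible(dir)
}

lfc_breaks <- c(-Inf, -3, -2, -1, -0.5, 0.5, 1, 2, 3, Inf)
lfc_colors <- c("blue", "navy", "cyan", "lightcyan", "white",
                "lightyellow", "yellow", "orange", "red")

# Fold-change bin of each node, encoded as a fill color from deep blue
# (strong down-regulation) through white to red (fold change >= 3).
lfc_fill <- function(lfc) {
  lfc[is.na(lfc)] <- 0
  lfc_colors[cut(lfc, breaks = lfc_breaks, right = FALSE, labels = FALSE)]
}

#' Export a network as GraphML
#'
#' Nodes carry z-score, p-value, log fold change, roles, localizations and
#' a fill color encoding the fold-change bin; edges carry kind and
#' reliability.
#'
#' @param x an `omics_network` or `trs_network`.
#' @param path output file.
#' @param net for a `trs_network`, the `omics_network` providing node
#'   annotation.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(x, path, net = NULL) {
  if (inherits(x, "trs_network")) {
    stopifnot(!is.null(net))
    nodes <- net$nodes[match(x$nodes, net$nodes$gene_id), , drop = FALSE]
    edges <- x$edges
  } else {
    nodes <- x$nodes
    edges <- x$edges
  }
  v <- data.frame(
    name = nodes$gene_id,
    z = nodes$z_score,
    p = ifelse(is.na(nodes$p_value), 1, nodes$p_value),
    logFC = ifelse(is.na(nodes$log_fold_change), 0, nodes$log_fold_change),
    roles = paste0(ifelse(nodes$is_start, "start", ""),
                   ifelse(nodes$is_start & nodes$is_end, ";", ""),
                   ifelse(nodes$is_end, "end", "")),
    localizations = nodes$localizations,
    fill = lfc_fill(nodes$log_fold_change),
    stringsAsFactors = FALSE)
  e <- data.frame(from = edges$source, to = edges$target,
                  kind = edges$kind,
                  reliability = ifelse(is.na(edges$reliability), -1,
                                       edges$reliability),
                  stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
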