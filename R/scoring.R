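#' Convert a p-value to a z-score
#'
#' \eqn{z = \Phi^{-1}(1 - p)}, the inverse standard-normal CDF at `1 - p`.
#' Values at or beyond the boundaries are clamped to `[eps, 1 - eps]`
#' (eps = 1e-16) so extreme p-values map to large finite deviates.
#'
#' @param p numeric vector of p-values.
#' @return Numeric vector of z-scores.
#' @examples
#' z_from_p(c(0.5, 0.05))
#' @export
z_from_p <- function(p) {
  eps <- 1e-16
  out_of_range <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(out_of_range)) {
    message(sprintf("%d p-value(s) clamped to (0, 1)", sum(out_of_range)))
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Aggregate z-scores of a gene set
#'
#' \eqn{Z_N = \sum_i z_i / \sqrt{k}} over the k members. Under independent
#' standard-normal member scores the aggregate is again standard normal,
#' which makes scores comparable across set sizes.
#'
#' @param z_values numeric vector (non-empty).
#' @return The aggregate z-score.
#' @export
aggregate_z <- function(z_values) {
  if (length(z_values) == 0) stop("cannot aggregate an empty z-score set")
  sum(z_values) / sqrt(length(z_values))
}

#' Build a Monte-Carlo background table for size-corrected scores
#'
#' For each set size k in `1:k_max`, draws `n_samples` random size-k subsets
#' of the value pool (without replacement within a subset), computes the
#' aggregate score \eqn{\sum x / \sqrt k}, and records its mean \eqn{\mu_k}
#' and standard deviation \eqn{\sigma_k}. Both sequences are then smoothed
#' by a centered moving average of width `window`, truncated at the ends, to
#' reduce Monte-Carlo noise across neighbouring sizes.
#'
#' @param values numeric pool (e.g. all network genes' z-scores, or all
#'   retained PPI reliabilities).
#' @param k_max largest set size to tabulate.
#' @param n_samples Monte-Carlo samples per size (default 100000).
#' @param window moving-average width (default 5; 1 disables smoothing).
#' @param seed integer seed for reproducibility.
#' @param kind label stored with the table (`"node_z"` or `"edge_reliability"`).
#' @return A `background_table`: data.frame with columns `k`, `mu`, `sigma`,
#'   `mu_smoothed`, `sigma_smoothed` and attributes recording the settings.
#' @export
build_background <- function(values, k_max, n_samples = 100000L, window = 5L,
                             seed = NULL, kind = "node_z") {
  n_pool <- length(values)
  if (n_pool < k_max) stop("value pool smaller than k_max")
  if (n_samples < 1000) stop("n_samples must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  mu <- sigma <- numeric(k_max)
  for (k in seq_len(k_max)) {
    sums <- if (k == 1) {
      values[sample.int(n_pool, n_samples, replace = TRUE)]
    } else {
      agg_sample_sums(values, k, n_samples)
    }
    agg <- sums / sqrt(k)
    mu[k] <- mean(agg)
    sigma[k] <- stats::sd(agg)
  }
  mu_s <- moving_average(mu, window)
  sigma_s <- moving_average(sigma, window)
  if (any(sigma_s <= 0)) stop("degenerate value pool: zero background SD")
  tab <- data.frame(k = seq_len(k_max), mu = mu, sigma = sigma,
                    mu_smoothed = mu_s, sigma_smoothed = sigma_s)
  attr(tab, "kind") <- kind
  attr(tab, "n_samples") <- n_samples
  attr(tab, "window") <- window
  attr(tab, "seed") <- seed
  class(tab) <- c("background_table", "data.frame")
  tab
}

# n_samples sums of k values drawn without replacement within each subset.
# Draws with replacement in a vectorized pass, then redraws the (rare) rows
# containing duplicates, so the subsets are exact uniform k-subsets.
agg_sample_sums <- function(values, k, n_samples) {
  n_pool <- length(values)
  idx <- matrix(sample.int(n_pool, n_samples * k, replace = TRUE),
                nrow = n_samples, ncol = k)
  # duplicate detection: sort within rows (vectorized), compare neighbours
  srt <- matrix(idx[order(row(idx), idx)], nrow = n_samples, byrow = TRUE)
  dup_row <- rowSums(srt[, -1L, drop = FALSE] == srt[, -k, drop = FALSE]) > 0
  for (i in which(dup_row)) idx[i, ] <- sample.int(n_pool, k)
  rowSums(matrix(values[idx], nrow = n_samples))
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Background-corrected score of a gene or edge set
#'
#' \eqn{S = (Z_N - \mu_k) / \sigma_k} using the smoothed background
#' estimates, so that random sets of any tabulated size score with mean 0
#' and standard deviation 1.
#'
#' @param raw the aggregate score of the set.
#' @param k set size.
#' @param bg a `background_table` covering size k.
#' @return The corrected score.
#' @export
corrected_score <- function(raw, k, bg) {
  if (k < 1 || k > nrow(bg)) {
    stop(sprintf("set size %d outside background table range 1..%d", k, nrow(bg)))
  }
  (raw - bg$mu_smoothed[k]) / bg$sigma_smoothed[k]
}

#' Expression score of a pathway
#'
#' \eqn{T(N) = S(N) + Z_{start} + Z_{end}}, where S(N) is the
#' background-corrected aggregate z over all pathway members. Adding the
#' terminal z-scores favours paths whose initiating signal and final
#' effector are themselves transcriptionally induced, which makes the
#' top-ranked paths biologically explicable.
#'
#' @param z path members' z-scores, in path order (length >= 2).
#' @param bg_nodes node-z `background_table`.
#' @return list with components `T` and `S`.
#' @export
path_expression_score <- function(z, bg_nodes) {
  if (length(z) < 2) stop("a pathway has at least two nodes")
  S <- corrected_score(aggregate_z(z), length(z), bg_nodes)
  list(T = S + z[1] + z[length(z)], S = S)
}

#' Reliability score of a pathway
#'
#' Background-corrected aggregate of the path's PPI edge reliabilities,
#' computed with the same aggregation and correction as the expression
#' score. PD edges carry no reliability and are excluded; a path with no
#' PPI edge scores 0.
#'
#' @param reliabilities reliabilities of the path's PPI edges.
#' @param bg_edges edge-reliability `background_table`.
#' @return The reliability score R.
#' @export
path_reliability_score <- function(reliabilities, bg_edges) {
  m <- length(reliabilities)
  if (m == 0) return(0)
  corrected_score(aggregate_z(reliabilities), m, bg_edges)
}

#' Combine expression and reliability into the path score
#'
#' @param T expression score.
#' @param R reliability score.
#' @return list with components `T`, `R` and `P = T + R`.
#' @export
path_score <- function(T, R) {
  list(T = T, R = R, P = T + R)
}

#' Composite score of a TRS Network
#'
#' \eqn{SF = (S + \sum_i P_i) / |E|}: rewards differential expression of the
#' member genes (S) and the significant pathways the network contains
#' (the sum of their path scores), and penalizes network size through the
#' edge count. Nodes and edges belonging to no member pathway contribute to
#' S and |E| only; they interconnect pathways.
#'
#' @param S corrected expression score of all network nodes.
#' @param pathway_scores path scores P of the member pathways.
#' @param n_edges number of network edges (>= 1).
#' @return The network score SF.
#' @export
network_score <- function(S, pathway_scores, n_edges) {
  if (n_edges < 1) stop("network score requires at least one edge")
  (S + sum(pathway_scores)) / n_edges
}

#' Write or read a background table as TSV
#'
#' The header carries the generation settings as `# key: value` comment
#' lines (kind, n_samples, window, seed).
#'
#' @param bg a `background_table`.
#' @param path output file.
#' @return `write_background` returns `path` invisibly; `read_background`
#'   returns the table.
#' @export
write_background <- function(bg, path) {
  meta <- sprintf("# %s: %s", c("kind", "n_samples", "window", "seed"),
                  c(attr(bg, "kind"), attr(bg, "n_samples"),
                    attr(bg, "window"), attr(bg, "seed") %||% "NA"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(as.data.frame(bg), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- strsplit(sub("^# ", "", meta_lines), ": ")
  meta <- stats::setNames(vapply(meta, `[`, character(1), 2),
                          vapply(meta, `[`, character(1), 1))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  attr(tab, "kind") <- meta[["kind"]]
  attr(tab, "n_samples") <- as.integer(meta[["n_samples"]])
  attr(tab, "window") <- as.integer(meta[["window"]])
  attr(tab, "seed") <- if (identical(meta[["seed"]], "NA")) NULL else as.integer(meta[["seed"]])
  class(tab) <- c("background_table", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
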