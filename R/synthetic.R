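# Synthetic omics-network scenarios with planted TRS Pathways.
#
# The generator emulates the statistical structure the method assumes: a
# degree-heterogeneous PPI background (PPI networks have hubs), a layer of
# protein-DNA edges out of nucleus-localized factors, and one or more
# planted signaling chains whose members are transcriptionally induced. A
# cross-link plants the transcription-mediated cross-talk the network
# search is designed to recover: the transcription factor ending one chain
# induces the expression of the start protein of the next.

#' Define a planted-pathway scenario
#'
#' @param n_genes number of genes (default 300).
#' @param n_ppi number of undirected background+planted PPI pairs (1500).
#' @param n_pd number of directed protein-DNA edges (150), including any
#'   cross-links.
#' @param planted list of planted chains, each `list(length =, effect =)`;
#'   default two 5-node chains with a mean z shift of 2.5.
#' @param cross_link logical; plant a PD edge from the end (transcription
#'   factor) of each chain to the start of the next (default TRUE). The
#'   cross-link target start gene is generated as an up-regulated DEG: the
#'   induced start protein is the planted phenomenon, not a noisy outcome.
#' @param deg_fraction_null expected DEG fraction among background genes at
#'   cutoff 0.05; the default 0.05 is the pure null (uniform p-values), and
#'   larger values add spurious strongly-shifted genes.
#' @param n_decoy_starts,n_decoy_ends extra role genes without planted
#'   signal (default 6 each).
#' @param seed integer seed; every generated artefact is deterministic
#'   given it.
#' @return A `trs_scenario` list of settings.
#' @export
trs_scenario <- function(n_genes = 300L, n_ppi = 1500L, n_pd = 150L,
                         planted = list(list(length = 5L, effect = 2.5),
                                        list(length = 5L, effect = 2.5)),
                         cross_link = TRUE, deg_fraction_null = 0.05,
                         n_decoy_starts = 6L, n_decoy_ends = 6L, seed = 1L) {
  total_planted <- sum(vapply(planted, function(p) p$length, numeric(1)))
  if (n_genes < total_planted) stop("n_genes smaller than total planted nodes")
  if (any(vapply(planted, function(p) p$length, numeric(1)) > 11)) {
    stop("a planted chain longer than 11 nodes cannot satisfy the length constraint")
  }
  if (any(vapply(planted, function(p) p$effect, numeric(1)) < 0)) {
    stop("effect sizes must be non-negative")
  }
  structure(list(n_genes = n_genes, n_ppi = n_ppi, n_pd = n_pd,
                 planted = planted, cross_link = cross_link,
                 deg_fraction_null = deg_fraction_null,
                 n_decoy_starts = n_decoy_starts, n_decoy_ends = n_decoy_ends,
                 seed = as.integer(seed)),
            class = "trs_scenario")
}

#' Generate the network side of a scenario
#'
#' Produces PPI pairs, PD edges, localization and role annotations, and
#' per-pair reliabilities. Planted chains are layered along the direction
#' of signal flow (start at the plasma membrane, middle members in the
#' cytoplasm, end in the nucleus) so they survive the localization filter.
#' Background PPI endpoints are drawn with heavy-tailed node weights
#' (configuration-model-like) to mimic PPI hubs. Planted PPI edges get
#' reliability 0.95 (coimmunoprecipitation-grade interactions); background
#' reliabilities are Beta(2, 3.3), calibrated so that the standard 0.6
#' reliability threshold sits near the 85th percentile — the operating
#' point reported for real PPI corpora — under which most background edges
#' are dropped by the reliability filter.
#'
#' @param sc a `trs_scenario`.
#' @return A `trs_scenario_data` list with data.frames `ppi_pairs`,
#'   `pd_edges`, `localizations`, `reliability`, vectors `starts`, `ends`,
#'   the planted chains, and the scenario.
#' @export
generate_network <- function(sc) {
  stopifnot(inherits(sc, "trs_scenario"))
  set.seed(sc$seed)
  n <- sc$n_genes
  genes <- sprintf("g%04d", seq_len(n))

  lens <- vapply(sc$planted, function(p) p$length, integer(1))
  planted_nodes <- sample(genes, sum(lens))
  chains <- split(planted_nodes, rep(seq_along(lens), lens))
  chains <- lapply(chains, unname)

  loc <- stats::setNames(rep("", n), genes)
  pool_probs <- c(extracellular = 0.08, plasma_membrane = 0.22,
                  cytoplasm = 0.40, nucleus = 0.20, other = 0.10)
  loc[] <- sample(names(pool_probs), n, replace = TRUE, prob = pool_probs)
  dual <- stats::runif(n) < 0.15 & loc == "cytoplasm"
  loc[dual] <- "cytoplasm;nucleus"
  loc[stats::runif(n) < 0.05] <- ""
  for (ch in chains) {
    k <- length(ch)
    loc[ch[1]] <- "plasma_membrane"
    if (k > 2) loc[ch[2:(k - 1)]] <- "cytoplasm"
    loc[ch[k]] <- "nucleus"
  }

  planted_pairs <- do.call(rbind, lapply(chains, function(ch) {
    data.frame(source = ch[-length(ch)], target = ch[-1],
               stringsAsFactors = FALSE)
  }))
  pkey <- paste(pmin(planted_pairs$source, planted_pairs$target),
                pmax(planted_pairs$source, planted_pairs$target), sep = "\r")

  n_bg <- sc$n_ppi - nrow(planted_pairs)
  w <- stats::runif(n)^(-0.45)            # heavy-tailed degree propensities
  w <- pmin(w, stats::quantile(w, 0.995))
  bg <- matrix(character(0), ncol = 2)
  seen <- character(0)
  while (nrow(bg) < n_bg) {
    m <- 2L * (n_bg - nrow(bg)) + 10L
    s <- sample(genes, m, replace = TRUE, prob = w)
    t <- sample(genes, m, replace = TRUE, prob = w)
    ok <- s != t
    s <- s[ok]; t <- t[ok]
    key <- paste(pmin(s, t), pmax(s, t), sep = "\r")
    # background edges never join two planted members: the planted chains'
    # topology, and the purely transcriptional nature of their cross-talk,
    # are the ground truth the scenario asserts
    both_planted <- s %in% planted_nodes & t %in% planted_nodes
    new <- !(key %in% c(seen, pkey)) & !duplicated(key) & !both_planted
    bg <- rbind(bg, cbind(s[new], t[new]))
    seen <- c(seen, key[new])
  }
  bg <- bg[seq_len(n_bg), , drop = FALSE]
  ppi_pairs <- rbind(planted_pairs,
                     data.frame(source = bg[, 1], target = bg[, 2],
                                stringsAsFactors = FALSE))
  ppi_pairs$provenance <- "synthetic"
  ppi_pairs$paper_count <- stats::rpois(nrow(ppi_pairs), 2)

  # PD edges out of nucleus-localized factors; cross-links first
  cross <- NULL
  if (sc$cross_link && length(chains) > 1) {
    cross <- data.frame(
      source = vapply(chains[-length(chains)], function(ch) ch[length(ch)],
                      character(1)),
      target = vapply(chains[-1], function(ch) ch[1], character(1)),
      stringsAsFactors = FALSE)
  }
  tf_pool <- genes[grepl("nucleus", loc)]
  n_bg_pd <- sc$n_pd - if (is.null(cross)) 0L else nrow(cross)
  pd_src <- sample(tf_pool, n_bg_pd, replace = TRUE)
  pd_tgt <- sample(genes, n_bg_pd, replace = TRUE)
  ok <- pd_src != pd_tgt
  pd_edges <- rbind(cross, data.frame(source = pd_src[ok], target = pd_tgt[ok],
                                      stringsAsFactors = FALSE))
  pd_edges <- pd_edges[!duplicated(paste(pd_edges$source, pd_edges$target)), ,
                       drop = FALSE]
  pd_edges$provenance <- "synthetic"
  pd_edges$paper_count <- 0L
  pd_edges$pd_sign <- "unknown"

  heads <- vapply(chains, `[`, character(1), 1)
  tails <- vapply(chains, function(ch) ch[length(ch)], character(1))
  start_pool <- setdiff(genes[loc %in% c("plasma_membrane", "extracellular")],
                        planted_nodes)
  end_pool <- setdiff(genes[grepl("nucleus", loc)], planted_nodes)
  starts <- unname(c(heads, sample(start_pool, min(sc$n_decoy_starts,
                                                   length(start_pool)))))
  ends <- unname(c(tails, sample(end_pool, min(sc$n_decoy_ends,
                                               length(end_pool)))))

  rel_key <- paste(pmin(ppi_pairs$source, ppi_pairs$target),
                   pmax(ppi_pairs$source, ppi_pairs$target), sep = "\r")
  reliability <- data.frame(
    source = pmin(ppi_pairs$source, ppi_pairs$target),
    target = pmax(ppi_pairs$source, ppi_pairs$target),
    mean_reliability = ifelse(rel_key %in% pkey, 0.95,
                              stats::rbeta(nrow(ppi_pairs), 2, 3.3)),
    stringsAsFactors = FALSE)

  loc_rows <- data.frame(gene_id = rep(genes, lengths(strsplit(loc, ";"))),
                         localization = unlist(strsplit(loc, ";")),
                         stringsAsFactors = FALSE)
  structure(list(scenario = sc, genes = genes, chains = chains,
                 ppi_pairs = ppi_pairs, pd_edges = pd_edges,
                 localizations = loc_rows, starts = starts, ends = ends,
                 reliability = reliability),
            class = "trs_scenario_data")
}

#' Generate the expression table of a scenario
#'
#' Background genes draw z from a standard normal and planted members from
#' Normal(effect, 1); p-values are the one-sided upper tail
#' \eqn{p = 1 - \Phi(z)} and the log fold change is `0.5 * z`, so its sign
#' always matches the z-score. Cross-link target start genes are drawn from
#' the effect distribution truncated to the DEG region (see
#' [trs_scenario()]). When `deg_fraction_null` exceeds the cutoff, the
#' excess fraction of background genes is shifted to produce spurious DEGs.
#'
#' @param scd a `trs_scenario_data`.
#' @param deg_cutoff DEG p-value cutoff used to place the truncation
#'   (default 0.05).
#' @return data.frame `gene_id`, `p_value`, `log_fold_change`, with the true
#'   z-scores in attribute `"z"`.
#' @export
generate_expression <- function(scd, deg_cutoff = 0.05) {
  stopifnot(inherits(scd, "trs_scenario_data"))
  sc <- scd$scenario
  set.seed(sc$seed + 104729L)
  n <- length(scd$genes)
  z <- stats::setNames(stats::rnorm(n), scd$genes)
  extra <- max(0, sc$deg_fraction_null - deg_cutoff)
  if (extra > 0) {
    spurious <- stats::runif(n) < extra / (1 - deg_cutoff)
    spurious <- spurious & !(scd$genes %in% unlist(scd$chains))
    z[spurious] <- stats::rnorm(sum(spurious), mean = 3)
  }
  for (i in seq_along(scd$chains)) {
    ch <- scd$chains[[i]]
    z[ch] <- stats::rnorm(length(ch), mean = sc$planted[[i]]$effect)
  }
  if (sc$cross_link && length(scd$chains) > 1) {
    thr <- stats::qnorm(1 - deg_cutoff)
    for (i in seq_along(scd$chains)[-1]) {
      head_i <- scd$chains[[i]][1]
      effect <- sc$planted[[i]]$effect
      repeat {
        zi <- stats::rnorm(1, mean = effect)
        if (zi > thr) break
      }
      z[head_i] <- zi
    }
  }
  out <- data.frame(gene_id = scd$genes,
                    p_value = stats::pnorm(z, lower.tail = FALSE),
                    log_fold_change = 0.5 * z,
                    stringsAsFactors = FALSE)
  attr(out, "z") <- z
  out
}

#' Generate simulated reliability training data
#'
#' Draws edge features from simple parametric distributions (paper counts
#' Poisson(2), expression correlations on the unit interval around zero,
#' clustering Beta(2, 5),
#' co-localization Bernoulli(0.3)) and labels from
#' Bernoulli(logistic(beta . x)), enabling coefficient-recovery tests.
#'
#' @param sc a `trs_scenario` (its seed drives the draw).
#' @param true_betas numeric(5): intercept and the four feature
#'   coefficients.
#' @param n_edges number of simulated pairs (default 5000).
#' @return list with `features` (data.frame), `labels` (0/1 vector) and
#'   `true_betas`.
#' @export
generate_reliability_data <- function(sc, true_betas, n_edges = 5000L) {
  stopifnot(length(true_betas) == 5)
  set.seed(sc$seed + 15485863L)
  features <- data.frame(
    source = sprintf("u%05d", seq_len(n_edges)),
    target = sprintf("v%05d", seq_len(n_edges)),
    paper_count = stats::rpois(n_edges, 2),
    expr_corr = 2 * stats::rbeta(n_edges, 2, 2) - 1,
    clustering = stats::rbeta(n_edges, 2, 5),
    coloc = stats::rbinom(n_edges, 1, 0.3),
    stringsAsFactors = FALSE)
  eta <- drop(cbind(1, feature_matrix(features)) %*% true_betas)
  labels <- stats::rbinom(n_edges, 1, stats::plogis(eta))
  list(features = features, labels = labels, true_betas = true_betas)
}

#' Assemble the analysis-ready network of a scenario
#'
#' Runs the standard preparation pipeline on generated scenario data:
#' build the directed network, attach localization, assign roles, apply the
#' localization filter, attach reliabilities and drop low-reliability PPIs,
#' and attach expression.
#'
#' @param scd a `trs_scenario_data`.
#' @param expression optional expression table (default:
#'   [generate_expression()] of the scenario).
#' @param deg_cutoff DEG cutoff (default 0.05).
#' @param reliability_threshold minimum PPI reliability (default 0.6).
#' @return An analysis-ready `omics_network`.
#' @export
prepare_scenario_network <- function(scd, expression = NULL,
                                     deg_cutoff = 0.05,
                                     reliability_threshold = 0.6) {
  if (is.null(expression)) expression <- generate_expression(scd, deg_cutoff)
  net <- build_network(ppi_edges = scd$ppi_pairs, pd_edges = scd$pd_edges)
  net <- attach_localization(net, scd$localizations)
  net <- assign_roles(net, scd$starts, scd$ends)
  net <- suppressMessages(localization_filter(net))
  net <- suppressMessages(
    filter_by_reliability(net, scd$reliability, threshold = reliability_threshold))
  attach_expression(net, expression, deg_cutoff = deg_cutoff)
}
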