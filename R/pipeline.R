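# End-to-end pipeline: build -> filter -> backgrounds -> pathway search ->
# network growth -> outputs, with a machine-readable provenance manifest.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], populated
#' with the standard settings: DEG cutoff 0.05, reliability threshold 0.6,
#' maximum path length 10, 100,000 Monte-Carlo background samples with a
#' width-5 smoothing window, and 1000 permutations.
#'
#' @param ... named overrides of any default.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # input file paths (NULL entries are generated from `simulate` instead)
    ppi = NULL, pd = NULL, localization = NULL, starts = NULL, ends = NULL,
    expression = NULL, reliability = NULL,
    simulate = NULL,             # a trs_scenario, used when file paths are NULL
    deg_cutoff = 0.05,
    reliability_threshold = 0.6,
    max_len = 10L,
    top_k = 5L,
    overgen = 20L,
    max_frontier = 4000L,
    n_background_samples = 100000L,
    window = 5L,
    n_perm = 1000L,
    run_permutations = FALSE,    # permutation p-values are expensive; opt in
    significance_cutoff = 0.05,
    start_gene = NULL,
    seed = NULL,
    output_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration field(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [pipeline_config()] fields.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the TRS discovery pipeline
#'
#' Executes the standard analysis: read (or simulate) the inputs, build and
#' annotate the directed omics network, apply the localization and
#' reliability filters, build the Monte-Carlo backgrounds, search top TRS
#' Pathways for all start/end pairs, grow and score the TRS Network, and
#' (optionally) attach permutation p-values. When `output_dir` is set, the
#' pathway table, network components, GraphML exports and a provenance
#' manifest are written there.
#'
#' @param cfg configuration list from [pipeline_config()] or
#'   [read_pipeline_config()]; `seed` is mandatory.
#' @return list with elements `network` (the scored `trs_network`),
#'   `pathways`, `net` (the filtered `omics_network`), `bg_nodes`,
#'   `bg_edges`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.null(cfg$seed)) stop("configuration field 'seed' is mandatory")
  set.seed(cfg$seed)

  sim <- NULL
  if (is.null(cfg$ppi)) {
    sim <- stage("simulate", {
      sc <- cfg$simulate %||% trs_scenario(seed = cfg$seed)
      generate_network(sc)
    })
    inputs <- list()
  } else {
    inputs <- list(ppi = cfg$ppi, pd = cfg$pd, localization = cfg$localization,
                   starts = cfg$starts, ends = cfg$ends,
                   expression = cfg$expression, reliability = cfg$reliability)
    inputs <- inputs[!vapply(inputs, is.null, logical(1))]
    if (is.null(cfg$expression)) stop("configuration field 'expression' is required")
  }

  net <- stage("build", {
    if (!is.null(sim)) {
      n <- build_network(ppi_edges = sim$ppi_pairs, pd_edges = sim$pd_edges)
      n <- attach_localization(n, sim$localizations)
      assign_roles(n, sim$starts, sim$ends)
    } else {
      n <- build_network(ppi_edges = read_edge_list(cfg$ppi),
                         pd_edges = if (is.null(cfg$pd)) NULL else read_edge_list(cfg$pd))
      if (!is.null(cfg$localization)) {
        n <- attach_localization(n, read_localizations(cfg$localization))
      }
      assign_roles(n, read_roles(cfg$starts), read_roles(cfg$ends))
    }
  })
  net <- stage("localization_filter", suppressMessages(localization_filter(net)))
  net <- stage("reliability_filter", {
    rel <- if (!is.null(sim)) sim$reliability
           else if (!is.null(cfg$reliability)) read_edge_list(cfg$reliability)
           else NULL
    if (is.null(rel)) net
    else suppressMessages(
      filter_by_reliability(net, rel, threshold = cfg$reliability_threshold))
  })
  net <- stage("expression", {
    tab <- if (!is.null(sim)) generate_expression(sim, cfg$deg_cutoff)
           else read_expression_table(cfg$expression)
    attach_expression(net, tab, deg_cutoff = cfg$deg_cutoff)
  })

  bg <- stage("backgrounds", {
    k_nodes <- max(cfg$max_len + 1L, min(nrow(net$nodes), 60L))
    bg_nodes <- build_background(net$nodes$z_score, k_max = k_nodes,
                                 n_samples = cfg$n_background_samples,
                                 window = cfg$window, seed = cfg$seed + 1L,
                                 kind = "node_z")
    rel_pool <- net$edges$reliability[net$edges$kind == "PPI"]
    rel_pool <- rel_pool[!is.na(rel_pool)]
    bg_edges <- if (length(rel_pool) >= cfg$max_len) {
      build_background(rel_pool, k_max = cfg$max_len,
                       n_samples = cfg$n_background_samples,
                       window = cfg$window, seed = cfg$seed + 2L,
                       kind = "edge_reliability")
    } else NULL
    list(nodes = bg_nodes, edges = bg_edges)
  })

  paths <- stage("pathway_search", {
    find_trs_pathways(net, bg$nodes, bg$edges, max_len = cfg$max_len,
                      top_k = cfg$top_k, overgen = cfg$overgen,
                      max_frontier = cfg$max_frontier)
  })
  if (isTRUE(cfg$run_permutations) && length(paths) > 0) {
    paths <- stage("pathway_permutations", {
      lapply(paths, pathway_pvalue, net = net, bg_nodes = bg$nodes,
             bg_edges = bg$edges, n_perm = cfg$n_perm,
             seed = cfg$seed + 3L, max_len = cfg$max_len,
             top_k = cfg$top_k, overgen = cfg$overgen,
             max_frontier = cfg$max_frontier)
    })
  }

  network <- stage("network_search", {
    if (length(paths) == 0) NULL else {
      g <- grow_trs_network(net, paths, start_gene = cfg$start_gene,
                            significance_cutoff = cfg$significance_cutoff)
      if (length(g$nodes) > nrow(bg$nodes)) {
        # grown network larger than the tabulated sizes: extend the table
        bg$nodes <- build_background(net$nodes$z_score,
                                     k_max = length(g$nodes),
                                     n_samples = cfg$n_background_samples,
                                     window = cfg$window,
                                     seed = cfg$seed + 1L, kind = "node_z")
      }
      score_trs_network(g, net, bg$nodes)
    }
  })
  if (isTRUE(cfg$run_permutations) && !is.null(network)) {
    network <- stage("network_permutations", {
      network_pvalue(network, net, bg$nodes, bg$edges, n_perm = cfg$n_perm,
                     seed = cfg$seed + 4L, max_len = cfg$max_len,
                     top_k = cfg$top_k, overgen = cfg$overgen,
                     max_frontier = cfg$max_frontier,
                     significance_cutoff = cfg$significance_cutoff)
    })
  }

  manifest <- list(
    parameters = cfg[c("deg_cutoff", "reliability_threshold", "max_len",
                       "top_k", "overgen", "max_frontier",
                       "n_background_samples", "window", "n_perm",
                       "significance_cutoff", "seed")],
    seeds = list(main = cfg$seed, bg_nodes = cfg$seed + 1L,
                 bg_edges = cfg$seed + 2L, pathway_perm = cfg$seed + 3L,
                 network_perm = cfg$seed + 4L),
    input_digests = if (length(inputs) > 0) {
      as.list(tools::md5sum(unlist(inputs)))
    } else list(simulated = TRUE),
    counts = list(nodes = nrow(net$nodes), edges = nrow(net$edges),
                  degs = sum(net$nodes$is_deg), pathways = length(paths),
                  network_nodes = if (is.null(network)) 0L else length(network$nodes))
  )

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(pathways_table(paths),
                       file.path(cfg$output_dir, "pathways.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_background(bg$nodes, file.path(cfg$output_dir, "background_nodes.tsv"))
    if (!is.null(bg$edges)) {
      write_background(bg$edges, file.path(cfg$output_dir, "background_edges.tsv"))
    }
    if (!is.null(network)) {
      comp <- data.frame(SF = network$SF, S = network$components$S,
                         P_sum = network$components$P_sum,
                         n_edges = network$components$n_edges,
                         p_value = as.numeric(network$p_value))
      utils::write.table(comp, file.path(cfg$output_dir, "network_components.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      export_graphml(network, file.path(cfg$output_dir, "trs_network.graphml"),
                     net = net)
    }
    yaml::write_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  }

  list(network = network, pathways = paths, net = net,
       bg_nodes = bg$nodes, bg_edges = bg$edges, manifest = manifest)
}
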