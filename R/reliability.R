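#' Compute the four reliability features of each PPI pair
#'
#' For every undirected PPI pair the features are: the number of papers in
#' which the interaction was observed; the Pearson correlation of the two
#' genes' expression profiles (0 when a profile is missing); the
#' small-world clustering statistic of the pair, taken as the mean of the
#' two endpoints' local (Watts-Strogatz) clustering coefficients on the
#' undirected PPI graph (0 for nodes of degree < 2); and a binary
#' co-localization flag, 1 when the two proteins share at least one
#' annotated subcellular compartment.
#'
#' @param net an `omics_network`.
#' @param expr_matrix optional numeric gene x sample matrix with gene ids as
#'   row names.
#' @param lit_counts optional data.frame (`source`, `target`, `n_papers`)
#'   overriding the edge `paper_count` values.
#' @return data.frame with one row per undirected PPI pair: `source`,
#'   `target` (sorted pair), `paper_count`, `expr_corr`, `clustering`,
#'   `coloc`.
#' @export
compute_edge_features <- function(net, expr_matrix = NULL, lit_counts = NULL) {
  stopifnot(inherits(net, "omics_network"))
  ppi <- net$edges[net$edges$kind == "PPI", , drop = FALSE]
  if (nrow(ppi) == 0) {
    return(data.frame(source = character(), target = character(),
                      paper_count = integer(), expr_corr = numeric(),
                      clustering = numeric(), coloc = numeric()))
  }
  a <- pmin(ppi$source, ppi$target)
  b <- pmax(ppi$source, ppi$target)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  pairs <- data.frame(source = a[first], target = b[first],
                      stringsAsFactors = FALSE)
  # per-pair paper count: max over the two directed records (they are merged
  # copies of the same undirected interaction)
  pc <- vapply(split(ppi$paper_count, key), max, numeric(1))
  pairs$paper_count <- as.integer(pc[key[first]])
  if (!is.null(lit_counts)) {
    lk <- paste(pmin(lit_counts$source, lit_counts$target),
                pmax(lit_counts$source, lit_counts$target), sep = "\r")
    m <- match(paste(pairs$source, pairs$target, sep = "\r"), lk)
    pairs$paper_count <- ifelse(is.na(m), 0L, as.integer(lit_counts$n_papers[m]))
  }

  pairs$expr_corr <- 0
  if (!is.null(expr_matrix)) {
    hit <- pairs$source %in% rownames(expr_matrix) &
      pairs$target %in% rownames(expr_matrix)
    if (any(hit)) {
      pairs$expr_corr[hit] <- vapply(which(hit), function(i) {
        r <- suppressWarnings(stats::cor(expr_matrix[pairs$source[i], ],
                                         expr_matrix[pairs$target[i], ]))
        if (is.na(r)) 0 else r
      }, numeric(1))
    }
  }

  g <- igraph::graph_from_data_frame(pairs[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = net$nodes$gene_id)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  names(cc) <- net$nodes$gene_id
  pairs$clustering <- (cc[pairs$source] + cc[pairs$target]) / 2

  locs <- strsplit(node_field(net, "localizations"), ";", fixed = TRUE)
  pairs$coloc <- as.numeric(mapply(function(u, v) {
    length(intersect(locs[[u]], locs[[v]])) > 0
  }, pairs$source, pairs$target))
  rownames(pairs) <- NULL
  pairs
}

feature_matrix <- function(features) {
  as.matrix(features[, c("paper_count", "expr_corr", "clustering", "coloc")])
}

#' Fit the logistic interaction-reliability model
#'
#' Maximum-likelihood logistic regression of interaction truth on the four
#' edge features, giving coefficients \eqn{\beta_0, \ldots, \beta_4}.
#' Aliased (constant) feature columns receive coefficient 0. Under complete
#' separation the fit falls back to a ridge-penalized estimate with a tiny
#' penalty (1e-8), with a warning.
#'
#' @param features data.frame as from [compute_edge_features()].
#' @param labels binary vector (1 = true interaction).
#' @return Named numeric vector of five coefficients
#'   (`intercept`, `paper_count`, `expr_corr`, `clustering`, `coloc`).
#' @export
fit_reliability_model <- function(features, labels) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  x <- feature_matrix(features)
  dat <- data.frame(y = labels, x)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  betas <- stats::coef(fit)
  if (separated) {
    warning("complete separation detected; using ridge-penalized fallback")
    betas <- ridge_logistic(x, labels, lambda = 1e-8)
  }
  betas[is.na(betas)] <- 0
  stats::setNames(as.numeric(betas),
                  c("intercept", "paper_count", "expr_corr", "clustering", "coloc"))
}

# L2-penalized logistic fit, used only as the separation fallback.
ridge_logistic <- function(x, y, lambda = 1e-8, max_iter = 100L) {
  if (requireNamespace("glmnet", quietly = TRUE) && ncol(x) >= 2) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    return(as.numeric(stats::coef(fit)))
  }
  X <- cbind(1, x)
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X * w, X) + diag(lambda, ncol(X))
    beta_new <- solve(H, crossprod(X * w, z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

predict_reliability <- function(betas, features) {
  eta <- drop(cbind(1, feature_matrix(features)) %*% betas)
  stats::plogis(eta)
}

#' Estimate mean PPI reliabilities over resampled trainings
#'
#' Repeats `n_repeats` times: draw `n_train` positive and `n_train` negative
#' training pairs (all available pairs are used, with a message, when a pool
#' is smaller), fit the logistic model, and score every PPI pair. The
#' per-pair mean and SD over repeats form the reliability estimates.
#'
#' @param net an `omics_network`.
#' @param features data.frame from [compute_edge_features()].
#' @param positives,negatives data.frames (`source`, `target`) of training
#'   pairs; matched to feature rows as unordered pairs.
#' @param n_repeats number of resampled trainings (default 1000).
#' @param n_train pairs drawn per class per repeat (default 5000).
#' @param seed integer seed.
#' @return A `reliability_model`: list with `betas` (mean coefficients over
#'   repeats), `n_repeats`, and `mean_reliability`, a data.frame
#'   (`source`, `target`, `mean_reliability`, `sd`).
#' @export
estimate_mean_reliability <- function(net, features, positives, negatives,
                                      n_repeats = 1000L, n_train = 5000L,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fkey <- paste(features$source, features$target, sep = "\r")
  row_of <- function(pairs) {
    k <- paste(pmin(pairs$source, pairs$target),
               pmax(pairs$source, pairs$target), sep = "\r")
    m <- match(k, fkey)
    m[!is.na(m)]
  }
  pos_rows <- row_of(positives)
  neg_rows <- row_of(negatives)
  if (length(pos_rows) == 0 || length(neg_rows) == 0) {
    stop("empty positive or negative training pool after matching to PPI pairs")
  }
  warned <- FALSE
  draw <- function(rows) {
    if (length(rows) < n_train) {
      if (!warned) {
        message(sprintf("training pool (%d) smaller than n_train (%d); using all",
                        length(rows), n_train))
        warned <<- TRUE
      }
      rows
    } else sample(rows, n_train)
  }
  acc <- matrix(0, nrow = nrow(features), ncol = 2)  # sum, sum of squares
  beta_sum <- numeric(5)
  for (r in seq_len(n_repeats)) {
    tr_pos <- draw(pos_rows); tr_neg <- draw(neg_rows)
    tr <- c(tr_pos, tr_neg)
    lab <- c(rep(1, length(tr_pos)), rep(0, length(tr_neg)))
    betas <- suppressWarnings(fit_reliability_model(features[tr, , drop = FALSE], lab))
    beta_sum <- beta_sum + betas
    p <- predict_reliability(betas, features)
    acc[, 1] <- acc[, 1] + p
    acc[, 2] <- acc[, 2] + p^2
  }
  mean_rel <- acc[, 1] / n_repeats
  var_rel <- pmax(acc[, 2] / n_repeats - mean_rel^2, 0)
  out <- data.frame(source = features$source, target = features$target,
                    mean_reliability = mean_rel,
                    sd = sqrt(var_rel * n_repeats / max(n_repeats - 1, 1)),
                    stringsAsFactors = FALSE)
  structure(list(betas = beta_sum / n_repeats, n_repeats = n_repeats,
                 mean_reliability = out),
            class = "reliability_model")
}

#' Remove low-reliability PPI edges
#'
#' Drops PPI edges whose mean reliability is below `threshold` (strict:
#' exactly-at-threshold edges are kept). PD edges are untouched. PPI edges
#' not covered by the model are removed and counted in a message.
#'
#' @param net an `omics_network`.
#' @param model a `reliability_model` (or a data.frame with columns
#'   `source`, `target`, `mean_reliability`).
#' @param threshold minimum reliability (default 0.6).
#' @param exempt_provenance optional character vector: PPI edges whose
#'   provenance contains any of these tags bypass the filter (e.g. curated
#'   pathway databases).
#' @return The filtered network with the `reliability` edge column filled.
#' @export
filter_by_reliability <- function(net, model, threshold = 0.6,
                                  exempt_provenance = NULL) {
  stopifnot(inherits(net, "omics_network"))
  rel <- if (inherits(model, "reliability_model")) model$mean_reliability else model
  net <- set_edge_reliability(net, rel)
  e <- net$edges
  is_ppi <- e$kind == "PPI"
  uncovered <- is_ppi & is.na(e$reliability)
  if (any(uncovered)) {
    message(sprintf("%d PPI edge(s) without reliability estimate removed",
                    sum(uncovered)))
  }
  exempt <- rep(FALSE, nrow(e))
  if (!is.null(exempt_provenance)) {
    pat <- paste(exempt_provenance, collapse = "|")
    exempt <- is_ppi & grepl(pat, e$provenance)
  }
  keep <- !is_ppi | exempt | (!is.na(e$reliability) & e$reliability >= threshold)
  net$edges <- e[keep, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

#' @export
print.reliability_model <- function(x, ...) {
  cat(sprintf("reliability model: %d repeats, %d PPI pairs\n",
              x$n_repeats, nrow(x$mean_reliability)))
  print(round(x$betas, 4))
  invisible(x)
}

#' Write per-pair mean reliabilities as TSV
#'
#' @param model a `reliability_model`.
#' @param path output file.
#' @export
write_reliability <- function(model, path) {
  utils::write.table(model$mean_reliability, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
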