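make_feature_net <- function() {
  # triangle A-B-C plus pendant D attached to A
  ppi <- data.frame(source = c("A", "B", "A", "A"),
                    target = c("B", "C", "C", "D"))
  net <- build_network(ppi_edges = ppi)
  attach_localization(net, data.frame(
    gene_id = c("A", "B", "C", "D"),
    localization = c("cytoplasm", "cytoplasm", "nucleus", "extracellular")))
}

test_that("co-localization flag is 1 iff a compartment is shared", {
  net <- make_feature_net()
  f <- compute_edge_features(net)
  get <- function(a, b) f[f$source == a & f$target == b, ]
  expect_equal(get("A", "B")$coloc, 1)  # both cytoplasm
  expect_equal(get("A", "C")$coloc, 0)
  expect_equal(get("A", "D")$coloc, 0)
})

test_that("pair clustering is the mean of the endpoints' local coefficients", {
  net <- make_feature_net()
  f <- compute_edge_features(net)
  # B and C sit in a closed triangle: local clustering 1 each;
  # A has neighbours {B, C, D} with one of three possible ties: 1/3;
  # D has degree 1: defined as 0.
  bc <- f[f$source == "B" & f$target == "C", ]
  expect_equal(bc$clustering, 1)
  ab <- f[f$source == "A" & f$target == "B", ]
  expect_equal(ab$clustering, (1 / 3 + 1) / 2)
  ad <- f[f$source == "A" & f$target == "D", ]
  expect_equal(ad$clustering, (1 / 3 + 0) / 2)
})

test_that("identical expression profiles give correlation 1, missing give 0", {
  net <- make_feature_net()
  m <- rbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8), C = c(4, 3, 2, 1))
  f <- compute_edge_features(net, expr_matrix = m)
  expect_equal(f[f$source == "A" & f$target == "B", "expr_corr"], 1)
  expect_equal(f[f$source == "A" & f$target == "C", "expr_corr"], -1)
  expect_equal(f[f$source == "A" & f$target == "D", "expr_corr"], 0)
})

test_that("balanced intercept-only fits give a zero intercept", {
  f <- data.frame(source = "x", target = "y",
                  paper_count = 0L, expr_corr = 0, clustering = 0, coloc = 0)
  f <- f[rep(1, 100), ]
  betas <- fit_reliability_model(f, rep(c(1, 0), each = 50))
  expect_equal(unname(betas["intercept"]), 0, tolerance = 1e-8)
  expect_true(all(betas[-1] == 0))  # aliased columns
})

test_that("intercept-only fit equals the closed form log(n_pos/n_neg)", {
  f <- data.frame(paper_count = 0L, expr_corr = 0, clustering = 0, coloc = 0)
  f <- f[rep(1, 100), ]
  betas <- fit_reliability_model(f, rep(c(1, 0), c(75, 25)))
  expect_equal(unname(betas["intercept"]), log(3), tolerance = 1e-6)
})

test_that("simulated coefficients are recovered within three standard errors", {
  true_betas <- c(-0.5, 0.3, 1.0, 2.0, 0.8)
  sim <- generate_reliability_data(trs_scenario(seed = 5), true_betas,
                                   n_edges = 5000)
  betas <- fit_reliability_model(sim$features, sim$labels)
  # oracle: an independent IRLS fit with its asymptotic standard errors
  X <- cbind(1, as.matrix(sim$features[, c("paper_count", "expr_corr",
                                           "clustering", "coloc")]))
  b <- rep(0, 5)
  for (it in 1:50) {
    mu <- plogis(drop(X %*% b))
    W <- mu * (1 - mu)
    b_new <- b + solve(crossprod(X * W, X), crossprod(X, sim$labels - mu))
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
  }
  se <- sqrt(diag(solve(crossprod(X * (plogis(drop(X %*% b)) *
                                         (1 - plogis(drop(X %*% b)))), X))))
  expect_equal(unname(betas), unname(drop(b)), tolerance = 1e-4)
  expect_true(all(abs(betas - true_betas) <= 3 * se))
})

test_that("a single resampled repeat equals one direct fit", {
  withr::with_seed(41, {
    net <- random_test_net(20, edge_prob = 0.3, pd_frac = 0)
    f <- compute_edge_features(net)
    n_pairs <- nrow(f)
    pos <- f[seq_len(n_pairs %/% 2), c("source", "target")]
    neg <- f[(n_pairs %/% 2 + 1):n_pairs, c("source", "target")]
    f$coloc <- as.numeric(seq_len(n_pairs) <= n_pairs %/% 2)
  })
  model <- suppressMessages(
    estimate_mean_reliability(net, f, pos, neg, n_repeats = 1, n_train = 1000,
                              seed = 1))
  betas <- suppressWarnings(
    fit_reliability_model(rbind(f[seq_len(nrow(pos)), ],
                                f[nrow(pos) + seq_len(nrow(neg)), ]),
                          rep(c(1, 0), c(nrow(pos), nrow(neg)))))
  direct <- plogis(drop(cbind(1, as.matrix(f[, c("paper_count", "expr_corr",
                                                 "clustering", "coloc")])) %*% betas))
  expect_equal(model$mean_reliability$mean_reliability, unname(direct),
               tolerance = 1e-6)
})

test_that("mean reliabilities are reproducible and bounded", {
  withr::with_seed(42, {
    net <- random_test_net(15, edge_prob = 0.3, pd_frac = 0)
    f <- compute_edge_features(net)
    f$coloc <- rbinom(nrow(f), 1, 0.5)
    half <- nrow(f) %/% 2
    pos <- f[seq_len(half), c("source", "target")]
    neg <- f[(half + 1):nrow(f), c("source", "target")]
  })
  m1 <- suppressMessages(estimate_mean_reliability(net, f, pos, neg,
                                                   n_repeats = 5,
                                                   n_train = 5, seed = 9))
  m2 <- suppressMessages(estimate_mean_reliability(net, f, pos, neg,
                                                   n_repeats = 5,
                                                   n_train = 5, seed = 9))
  expect_identical(m1$mean_reliability, m2$mean_reliability)
  expect_true(all(m1$mean_reliability$mean_reliability >= 0 &
                    m1$mean_reliability$mean_reliability <= 1))
})

test_that("reliability filter drops strictly sub-threshold PPIs only", {
  ppi <- data.frame(source = c("A", "B"), target = c("B", "C"))
  pd <- data.frame(source = "C", target = "A")
  net <- build_network(ppi_edges = ppi, pd_edges = pd)
  rel <- data.frame(source = c("A", "B"), target = c("B", "C"),
                    mean_reliability = c(0.59, 0.60))
  filtered <- filter_by_reliability(net, rel, threshold = 0.6)
  e <- filtered$edges
  expect_false(any(e$source == "A" & e$kind == "PPI"))   # 0.59 removed
  expect_equal(sum(e$kind == "PPI"), 2)                  # B<->C kept at 0.60
  expect_equal(sum(e$kind == "PD"), 1)                   # PD untouched
})

test_that("raising the reliability threshold never adds edges", {
  withr::with_seed(43, {
    net <- random_test_net(15, edge_prob = 0.3)
  })
  rel <- data.frame(
    source = pmin(net$edges$source, net$edges$target),
    target = pmax(net$edges$source, net$edges$target),
    mean_reliability = runif(nrow(net$edges)))
  rel <- rel[!duplicated(paste(rel$source, rel$target)), ]
  prev <- suppressMessages(filter_by_reliability(net, rel, threshold = 0.2))
  for (thr in c(0.4, 0.6, 0.8)) {
    cur <- suppressMessages(filter_by_reliability(net, rel, threshold = thr))
    expect_true(all(paste(cur$edges$source, cur$edges$target, cur$edges$kind) %in%
                      paste(prev$edges$source, prev$edges$target, prev$edges$kind)))
    prev <- cur
  }
})
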