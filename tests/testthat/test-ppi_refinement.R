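test_that("clustering coefficient matches hand counts", {
  g <- toy_network()
  expect_equal(clustering_coefficient(g, "b"), 1.0)  # a,c adjacent
  expect_equal(clustering_coefficient(g, "d"), 0)    # degree 1
  star <- interaction_network(data.frame(from = "hub", to = c("x", "y", "z")))
  expect_equal(clustering_coefficient(star, "hub"), 0)
  # node with neighbors {b,c,d}, only b-c present among them
  g2 <- interaction_network(data.frame(
    from = c("a", "a", "a", "b"), to = c("b", "c", "d", "c")))
  expect_equal(clustering_coefficient(g2, "a"), 1 / 3)
  expect_error(clustering_coefficient(g, "zz"), "not in network")
})

test_that("edge features encode the four reliability signals", {
  g <- interaction_network(data.frame(from = c("g1", "g2"),
                                      to = c("g2", "g3"),
                                      observation_count = c(5L, 1L)))
  vals <- rbind(g1 = c(1, 2, 3, 4, 5, 6, 7, 8),
                g2 = c(1, 2, 3, 4, 5, 6, 7, 8),   # identical to g1
                g3 = c(2, 1, 4, 3, 6, 5, 8, 7))
  colnames(vals) <- paste0("s", 1:8)
  expr <- expression_bundle(vals, rep(c("WT", "MT"), each = 4))
  loc <- list(g1 = "nucleus", g2 = "nucleus", g3 = "membrane")
  feats <- compute_edge_features(g, expr, loc)
  r12 <- feats[feats$from == "g1", ]
  r23 <- feats[feats$from == "g2", ]
  expect_equal(r12$coexpr, 1.0)
  expect_equal(r12$localization, 1.0)
  expect_equal(r23$localization, 0.0)
  expect_equal(r12$obs_count, 5L)
  # missing localization/expression degrade to 0
  feats0 <- compute_edge_features(g, NULL, NULL)
  expect_true(all(feats0$coexpr == 0) && all(feats0$localization == 0))
})

make_separable_features <- function(n_pos = 40, n_neg = 40, seed = 1) {
  withr::with_seed(seed, {
    pos <- sprintf("p%03d|q%03d", seq_len(n_pos), seq_len(n_pos))
    neg <- sprintf("u%03d|v%03d", seq_len(n_neg), seq_len(n_neg))
    keys <- c(pos, neg)
    parts <- strsplit(keys, "|", fixed = TRUE)
    feats <- data.frame(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 2),
      obs_count = c(rep(5L, n_pos), rep(0L, n_neg)),
      coexpr = 0, clustering = 0, localization = 0,
      stringsAsFactors = FALSE)
    list(features = feats, positives = pos, negatives = neg)
  })
}

test_that("reliability model separates a separable fixture perfectly", {
  fx <- make_separable_features()
  m <- train_reliability_model(fx$features, fx$positives, fx$negatives,
                               n_repeats = 20, seed = 3)
  expect_true(all(m$holdout$accuracy == 1))
  expect_true(all(m$holdout$auc == 1))
  prob <- predict_reliability(m, fx$features)
  expect_true(all((prob >= m$cutoff) == c(rep(TRUE, 40), rep(FALSE, 40))))
})

test_that("reliability model has no signal on identical class distributions", {
  withr::with_seed(9, {
    keys <- sprintf("a%03d|b%03d", 1:100, 1:100)
    parts <- strsplit(keys, "|", fixed = TRUE)
    feats <- data.frame(from = vapply(parts, `[[`, "", 1),
                        to = vapply(parts, `[[`, "", 2),
                        obs_count = rpois(100, 3), coexpr = runif(100, -1, 1),
                        clustering = runif(100), localization = runif(100))
  })
  m <- train_reliability_model(feats, keys[1:50], keys[51:100],
                               n_repeats = 40, seed = 5)
  expect_gt(mean(m$holdout$accuracy), 0.3)
  expect_lt(mean(m$holdout$accuracy), 0.7)
  expect_gt(m$cutoff, 0.2); expect_lt(m$cutoff, 0.8)
})

test_that("training is deterministic given the seed and validates labels", {
  fx <- make_separable_features()
  m1 <- train_reliability_model(fx$features, fx$positives, fx$negatives,
                                n_repeats = 10, seed = 7)
  m2 <- train_reliability_model(fx$features, fx$positives, fx$negatives,
                                n_repeats = 10, seed = 7)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$cutoff, m2$cutoff)
  expect_error(train_reliability_model(fx$features, fx$positives,
                                       c(fx$positives[1], fx$negatives),
                                       seed = 1), "overlap")
  expect_error(train_reliability_model(fx$features, fx$positives[1],
                                       fx$negatives, seed = 1), ">= 2")
})

test_that("filter_network keeps exactly above-cutoff edges and all nodes", {
  fx <- make_separable_features(n_pos = 10, n_neg = 10)
  net <- interaction_network(fx$features[, c("from", "to", "obs_count")] |>
                               stats::setNames(c("from", "to", "observation_count")))
  m <- train_reliability_model(fx$features, fx$positives, fx$negatives,
                               n_repeats = 5, seed = 1)
  res <- filter_network(net, m, fx$features)
  expect_setequal(petals:::edge_keys(res$network), fx$positives)
  expect_setequal(paste(res$removed$from, res$removed$to, sep = "|"),
                  fx$negatives)
  expect_equal(igraph::vcount(res$network), igraph::vcount(net))
  # degenerate cutoffs
  m_all <- m; m_all$coefficients[] <- 0  # every prob 0.5
  expect_equal(igraph::ecount(filter_network(net, m_all, fx$features,
                                             cutoff = 0.4)$network),
               igraph::ecount(net))
  expect_equal(igraph::ecount(filter_network(net, m_all, fx$features,
                                             cutoff = 0.6)$network), 0L)
})

test_that("family imputation adds exactly family-supported missing edges", {
  g <- interaction_network(data.frame(from = c("x", "q"), to = c("y", "r")),
                           nodes = c("a", "b"))
  fam <- list(x = "fam1", y = "fam2", a = "fam1", b = "fam2", q = "fam3")
  g2 <- impute_edges(g, fam)
  df <- network_edges(g2)
  imputed <- df[df$provenance == "imputed", ]
  # fam1-fam2 interacts (x-y): missing member pairs a-b, a-y, x-b imputed
  expect_setequal(paste(imputed$from, imputed$to, sep = "|"),
                  c("a|b", "a|y", "b|x"))
  expect_true(all(imputed$observation_count == 0L))
  # existing edge not duplicated, provenance stays observed
  expect_equal(df$provenance[df$from == "x" & df$to == "y"], "observed")
  # no family pair with unconnected members -> nothing to add
  expect_equal(igraph::ecount(impute_edges(g, list(q = "famA", r = "famB",
                                                   z = "famC"))),
               igraph::ecount(g))
})

test_that("refinement set algebra and imputation idempotence hold", {
  withr::with_seed(11, {
    g <- random_test_graph(8, 0.5)
    fam <- stats::setNames(as.list(sample(c("f1", "f2", "f3"),
                                          igraph::vcount(g), TRUE)),
                           igraph::V(g)$name)
    feats <- compute_edge_features(g)
    keys <- petals:::edge_keys(g)
    m <- train_reliability_model(
      feats, keys[seq_len(floor(length(keys) / 2))],
      keys[-seq_len(floor(length(keys) / 2))], n_repeats = 5, seed = 2)
    res <- filter_network(g, m, feats)
    ek <- petals:::edge_keys(g)
    ekp <- petals:::edge_keys(res$network)
    expect_true(all(ekp %in% ek))                          # E' subset E
    removed <- paste(res$removed$from, res$removed$to, sep = "|")
    expect_length(intersect(removed, ekp), 0)              # F disjoint E'
    g2 <- impute_edges(res$network, fam)
    expect_true(all(ekp %in% petals:::edge_keys(g2)))      # E'' superset E'
    g3 <- impute_edges(g2, fam)
    expect_identical(network_edges(g3), network_edges(g2)) # idempotent
  })
})
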