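test_that("shortest path distance and diameter bound follow the two-lookup rule", {
  g <- interaction_network(data.frame(from = c("a", "x", "y"),
                                      to = c("x", "y", "b")),
                           nodes = "z")
  expect_equal(shortest_path_distance(g, "a", "a"), 0L)
  expect_equal(shortest_path_distance(g, "a", "b"), 3L)
  expect_equal(shortest_path_distance(g, "a", "z"), Inf)
  expect_error(shortest_path_distance(g, "a", "nope"), "not in network")

  # raw distance wins even when the imputed network is shorter
  gi <- interaction_network(rbind(network_edges(g)[, 1:2],
                                  data.frame(from = "a", to = "b")))
  expect_equal(diameter_bound(g, gi, "a", "b"), 3L)
  # fallback to imputed only on disconnection
  gi2 <- interaction_network(rbind(network_edges(g)[, 1:2],
                                   data.frame(from = c("z", "q"),
                                              to = c("q", "b"))))
  expect_equal(diameter_bound(g, gi2, "a", "z"), 5L)
  expect_equal(diameter_bound(g, g, "a", "z"), Inf)
})

test_that("all_paths_dfs enumerates exactly the bounded simple paths", {
  # path graph: single path within bound
  pg <- interaction_network(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_equal(all_paths_dfs(pg, "a", "c", 2), list(c("a", "b", "c")))
  # 4-cycle: both sides
  cyc <- interaction_network(data.frame(from = c("a", "b", "c", "d"),
                                        to = c("b", "c", "d", "a")))
  expect_equal(all_paths_dfs(cyc, "a", "c", 2),
               list(c("a", "b", "c"), c("a", "d", "c")))
  # K4: 5 simple paths a->d with <= 3 edges
  k4 <- interaction_network(as.data.frame(t(combn(c("a", "b", "c", "d"), 2)) |>
                                            `colnames<-`(c("from", "to"))))
  expect_length(all_paths_dfs(k4, "a", "d", 3), 5L)
  expect_error(all_paths_dfs(k4, "a", "d", Inf), "finite")
})

test_that("all_paths_dfs equals brute-force enumeration on random graphs", {
  withr::with_seed(2024, {
    for (rep in 1:20) {
      n <- sample(4:8, 1)
      g <- random_test_graph(n, runif(1, 0.25, 0.6))
      vn <- igraph::V(g)$name
      ab <- sample(vn, 2)
      for (bound in 1:(n - 1)) {
        expect_identical(all_paths_dfs(g, ab[1], ab[2], bound),
                         brute_force_paths(g, ab[1], ab[2], bound))
      }
    }
  })
})

petal_world <- function(seed = 99) {
  # line a-b-c-d with strong coexpression and rules on every edge; decoy
  # route a-b-x-d with an uncorrelated, unannotated x; a rule-free chain
  # y1..y8 hanging off x so null path sampling is non-degenerate
  withr::with_seed(seed, {
    chain <- paste0("y", 1:8)
    net <- interaction_network(data.frame(
      from = c("a", "b", "c", "b", "x", "x", chain[-8]),
      to = c("b", "c", "d", "x", "d", chain[1], chain[-1])))
    f <- rnorm(12)
    vals <- rbind(a = f + rnorm(12, 0, 0.1), b = f + rnorm(12, 0, 0.1),
                  c = f + rnorm(12, 0, 0.1), d = f + rnorm(12, 0, 0.1),
                  x = rnorm(12))
    colnames(vals) <- paste0("s", 1:12)
    expr <- expression_bundle(vals, rep(c("WT", "MT"), each = 6))
    ann <- list(a = "t1", b = "t2", c = "t3", d = "t4")
    rules <- data.frame(termA = c("t1", "t2", "t3"),
                        termB = c("t2", "t3", "t4"), support = 1L)
    list(net = net, cm = pearson_map(expr), ann = ann, rules = rules)
  })
}

test_that("build_petal filters on gamma and p, merges survivors", {
  w <- petal_world()
  paths <- all_paths_dfs(w$net, "a", "d", 3)
  # p_threshold is looser than the 0.05 default because on a 13-node
  # graph a non-trivial share of null walks retrace the annotated path;
  # threshold calibration is exercised on the full-scale fixture in
  # test-acceptance.R
  pet <- build_petal("d", paths, w$cm, w$rules, w$ann, w$net,
                     gamma = 0.6, p_threshold = 0.15, n_null = 200, seed = 4)
  # the a-b-c-d path is coexpressed and rule-covered; a-x-d is not
  expect_true("b" %in% igraph::V(pet$graph)$name)
  expect_false("x" %in% igraph::V(pet$graph)$name)
  kept <- pet$paths[pet$paths$kept, ]
  expect_true(all(kept$r_phi >= 0.6 & kept$p_phi < 0.15))
  # every petal edge lies on a kept path; kept path edges are in the petal
  pek <- petals:::edge_keys(pet$graph)
  path_edges <- unlist(lapply(strsplit(kept$path, ";"), function(p) {
    paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]), sep = "|")
  }))
  expect_setequal(pek, unique(path_edges))
  # impossible gamma empties the petal
  pet0 <- build_petal("d", paths, w$cm, w$rules, w$ann, w$net,
                      gamma = 0.999, p_threshold = 0.05, n_null = 200,
                      seed = 4)
  expect_equal(igraph::vcount(pet0$graph), 0L)
})

test_that("mean absolute coexpression scores paths as specified", {
  cm <- structure(list(genes = c("a", "b", "c"),
                       matrix = matrix(c(1, 0.8, 0, 0.8, 1, -0.7,
                                         0, -0.7, 1), 3, 3,
                                       dimnames = list(c("a", "b", "c"),
                                                       c("a", "b", "c"))),
                       constant = character(0)),
                  class = "coexpression_map")
  net <- interaction_network(data.frame(from = c("a", "b"), to = c("b", "c")))
  ann <- list(); rules <- data.frame(termA = character(),
                                     termB = character(), support = integer())
  pet <- build_petal("c", list(c("a", "b", "c")), cm, rules, ann, net,
                     gamma = 0.74, p_threshold = 0.5, n_null = 100, seed = 1)
  expect_equal(pet$paths$r_phi, mean(c(0.8, 0.7)))
})

test_that("raising gamma or lowering p_threshold never grows the petal", {
  w <- petal_world()
  paths <- all_paths_dfs(w$net, "a", "d", 3)
  base <- build_petal("d", paths, w$cm, w$rules, w$ann, w$net,
                      gamma = 0.5, p_threshold = 0.2, n_null = 200, seed = 6)
  for (par in list(c(0.7, 0.2), c(0.5, 0.01), c(0.9, 0.01))) {
    tighter <- build_petal("d", paths, w$cm, w$rules, w$ann, w$net,
                           gamma = par[1], p_threshold = par[2],
                           n_null = 200, seed = 6)
    expect_true(all(igraph::V(tighter$graph)$name %in%
                      igraph::V(base$graph)$name))
    expect_true(all(petals:::edge_keys(tighter$graph) %in%
                      petals:::edge_keys(base$graph)))
  }
})

test_that("build_blossom skips unreachable candidates and is deterministic", {
  w <- petal_world()
  net2 <- interaction_network(rbind(network_edges(w$net)[, 1:2],
                                    data.frame(from = "lone1", to = "lone2")))
  b1 <- build_blossom("a", c("d", "lone2", "absent"), net2, net2, w$cm,
                      w$rules, w$ann, p_threshold = 0.15, n_null = 200,
                      seed = 3)
  expect_true("d" %in% names(b1$petals))
  expect_false("lone2" %in% names(b1$petals))  # disconnected from a
  expect_true(all(vapply(b1$petals, function(p)
    "a" %in% igraph::V(p$graph)$name, TRUE)))
  b2 <- build_blossom("a", c("d", "lone2", "absent"), net2, net2, w$cm,
                      w$rules, w$ann, p_threshold = 0.15, n_null = 200,
                      seed = 3)
  expect_identical(lapply(b1$petals, function(p) network_edges(p$graph)),
                   lapply(b2$petals, function(p) network_edges(p$graph)))
  expect_error(build_blossom("nope", "d", w$net, w$net, w$cm, w$rules,
                             w$ann), "driver not in network")
})

test_that("candidates connected only through imputed edges get petals", {
  # raw G: driver a - b (plus an unannotated background chain so the
  # null-path sampler has rule-free paths); candidate d attached only via
  # the imputed edge b-d
  raw <- interaction_network(data.frame(
    from = c("a", "b", "x1", "x2", "x3"),
    to = c("b", "x1", "x2", "x3", "x4")), nodes = "d")
  fam <- list(a = "f1", b = "f2", d = "f1")  # f1-f2 interact via a-b
  gi <- impute_edges(raw, fam)
  expect_true("b|d" %in% petals:::edge_keys(gi))
  w <- petal_world()
  ann <- list(a = "t1", b = "t2", d = "t3")
  rules <- data.frame(termA = c("t1", "t2"), termB = c("t2", "t3"),
                      support = 1L)
  cm <- structure(list(genes = c("a", "b", "d"),
                       matrix = matrix(0.9, 3, 3,
                                       dimnames = list(c("a", "b", "d"),
                                                       c("a", "b", "d"))),
                       constant = character(0)),
                  class = "coexpression_map")
  # the graph is tiny, so a sizeable share of null paths retrace the
  # observed route; a permissive rule threshold keeps the focus of this
  # test on imputed-edge handling
  bl <- build_blossom("a", "d", raw, gi, cm, rules, ann,
                      p_threshold = 0.45, n_null = 100, seed = 1)
  expect_true("d" %in% names(bl$petals))
  edf <- network_edges(bl$petals$d$graph)
  expect_true("imputed" %in% edf$provenance)
})
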