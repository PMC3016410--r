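# small graphs and bundles shared across test files

toy_network <- function() {
  # triangle a-b-c plus pendant d on a, isolated e
  interaction_network(
    data.frame(from = c("a", "b", "c", "a"),
               to = c("b", "c", "a", "d"),
               observation_count = c(3L, 1L, 2L, 1L)),
    nodes = "e")
}

toy_expression <- function(n_genes = 6, n_per_group = 4, seed = 42) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n_genes * 2 * n_per_group), nrow = n_genes,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   paste0("s", seq_len(2 * n_per_group))))
    expression_bundle(vals, rep(c("WT", "MT"), each = n_per_group))
  })
}

# independent brute-force simple path enumeration by DFS over edge lists
# kept deliberately separate from the package implementation
brute_force_paths <- function(network, a, b, max_len) {
  el <- igraph::as_edgelist(network, names = TRUE)
  nbrs <- function(v) unique(c(el[el[, 1] == v, 2], el[el[, 2] == v, 1]))
  found <- list()
  grow <- function(path) {
    tip <- path[length(path)]
    if (tip == b) { found[[length(found) + 1L]] <<- path; return(invisible()) }
    if (length(path) > max_len) return(invisible())
    for (w in nbrs(tip)) if (!w %in% path) grow(c(path, w))
  }
  if (a != b) grow(a)
  found[order(vapply(found, paste, "", collapse = "\r"))]
}

# random connected-ish graph on n nodes for property tests
random_test_graph <- function(n, p = 0.4) {
  nodes <- letters[seq_len(n)]
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  interaction_network(
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2]),
    nodes = nodes)
}

# tiny GO world: root -> {p1, p2}; p1 -> {t1, t2, t3}; p2 -> {t4, t5}
toy_go <- function() {
  go_graph(c("root", "p1", "p2", "t1", "t2", "t3", "t4", "t5"),
           data.frame(child = c("p1", "p2", "t1", "t2", "t3", "t4", "t5"),
                      parent = c("root", "root", "p1", "p1", "p1", "p2", "p2")))
}
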