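#' Unweighted shortest-path distance between two nodes
#'
#' Breadth-first search edge count; `Inf` when disconnected, 0 when
#' `a == b`.
#'
#' @param network `igraph` interaction network.
#' @param a,b node names.
#' @return integer edge count or `Inf`.
#' @export
shortest_path_distance <- function(network, a, b) {
  vn <- igraph::V(network)$name
  if (!a %in% vn) stop("node not in network: ", a)
  if (!b %in% vn) stop("node not in network: ", b)
  d <- igraph::distances(network, v = a, to = b, weights = NA)[1L, 1L]
  if (is.infinite(d)) Inf else as.integer(d)
}

#' Diameter bound for the path search
#'
#' The search bound d_i is the shortest-path distance between driver and
#' candidate in the raw network G; only when the pair is disconnected
#' there does the bound fall back to the distance in the imputed network.
#' Returns `Inf` only if the pair is disconnected in both, in which case
#' the candidate is skipped.
#'
#' @param G raw `igraph` network.
#' @param G_imputed imputed `igraph` network (G'').
#' @param a,b node names.
#' @return integer bound or `Inf`.
#' @export
diameter_bound <- function(G, G_imputed, a, b) {
  d <- shortest_path_distance(G, a, b)
  if (is.infinite(d)) d <- shortest_path_distance(G_imputed, a, b)
  d
}

#' Enumerate all bounded simple paths between two nodes
#'
#' Exhaustive depth-first search for every simple path from `a` to `b`
#' with edge count at most `max_len` (inclusive bound, so that whenever
#' the pair is connected within the bound at least one path is returned).
#' Output is a set: path order does not depend on internal traversal.
#'
#' @param network `igraph` interaction network.
#' @param a,b node names.
#' @param max_len maximum edge count, finite and >= 1.
#' @return list of character vectors (node sequences from `a` to `b`),
#'   sorted lexicographically.
#' @export
all_paths_dfs <- function(network, a, b, max_len) {
  if (!is.finite(max_len)) stop("max_len must be finite")
  stopifnot(max_len >= 1L)
  vn <- igraph::V(network)$name
  if (!a %in% vn) stop("node not in network: ", a)
  if (!b %in% vn) stop("node not in network: ", b)
  adj <- lapply(igraph::adjacent_vertices(network, vn), names)
  names(adj) <- vn
  out <- list()
  visit <- function(node, path) {
    if (node == b) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    if (length(path) > max_len) return()
    for (nb in adj[[node]]) {
      if (!nb %in% path) visit(nb, c(path, nb))
    }
  }
  if (a != b) visit(a, a)
  keys <- vapply(out, paste, "", collapse = "\r")
  out[order(keys)]
}

#' Score and merge paths into a petal
#'
#' Each candidate path is scored by (i) its mean absolute coexpression
#' r(phi), the average of |r| over consecutive node pairs, and (ii) the
#' rule-based significance p_phi from [path_significance()]. Paths with
#' r(phi) >= gamma and p_phi < p_threshold survive, and their node and
#' edge sets are merged into the petal; an empty petal is returned when no
#' path survives.
#'
#' @param candidate candidate gene the paths lead to.
#' @param paths list of node-sequence paths (as from [all_paths_dfs()]).
#' @param coexpr_map a `coexpression_map`.
#' @param rules rule table from [mine_rules()].
#' @param leaf_annotations leaf-restricted annotation map.
#' @param network `igraph` network used for null-path sampling and for
#'   edge provenance lookup (typically G'').
#' @param gamma coexpression threshold in (0, 1) (default 0.6).
#' @param p_threshold rule-significance threshold in (0, 1) (default 0.05).
#' @param n_null null paths per significance test.
#' @param seed integer seed.
#' @return object of class `petal`: list with `candidate`, `graph` (an
#'   `igraph`, empty when no path survives), and `paths` (a data.frame of
#'   all scored paths with columns `path`, `r_phi`, `rule_count`, `p_phi`,
#'   `kept`).
#' @export
build_petal <- function(candidate, paths, coexpr_map, rules, leaf_annotations,
                        network, gamma = 0.6, p_threshold = 0.05,
                        n_null = 1000L, seed = 1L) {
  stopifnot(gamma > 0, gamma < 1, p_threshold > 0, p_threshold < 1)
  n <- length(paths)
  score <- data.frame(path = vapply(paths, paste, "", collapse = ";"),
                      r_phi = numeric(n), rule_count = integer(n),
                      p_phi = numeric(n), kept = logical(n),
                      stringsAsFactors = FALSE)
  kept_paths <- list()
  matcher <- rule_matcher(rules, leaf_annotations)
  adj <- if (n > 0L) adjacency_list(network)
  # the null distribution of rule counts depends only on the edge count,
  # so one null sample per distinct path length serves every path of that
  # length (seeds derived from the master seed and the length)
  null_cache <- list()
  for (k in seq_len(n)) {
    phi <- paths[[k]]
    u <- phi[-length(phi)]; v <- phi[-1L]
    present <- u %in% coexpr_map$genes & v %in% coexpr_map$genes
    rvals <- rep(0, length(u))
    rvals[present] <- coexpr(coexpr_map, u[present], v[present])
    r_phi <- mean(abs(rvals))
    len <- length(phi) - 1L
    lkey <- as.character(len)
    if (is.null(null_cache[[lkey]])) {
      null_cache[[lkey]] <- null_rule_counts(len, matcher, adj, n_null,
                                             seed = derive_seed(seed, len))
    }
    nulls <- null_cache[[lkey]]
    obs <- matcher(phi)
    p_phi <- (1 + sum(nulls >= obs)) / (1 + length(nulls))
    keep <- r_phi >= gamma && p_phi < p_threshold
    score$r_phi[k] <- r_phi
    score$rule_count[k] <- as.integer(obs)
    score$p_phi[k] <- p_phi
    score$kept[k] <- keep
    if (keep) kept_paths[[length(kept_paths) + 1L]] <- phi
  }
  graph <- merge_paths(kept_paths, network)
  structure(list(candidate = candidate, graph = graph, paths = score),
            class = "petal")
}

# union of path edges, with provenance looked up from the search network
merge_paths <- function(paths, network) {
  if (!length(paths)) return(interaction_network())
  from <- unlist(lapply(paths, function(p) p[-length(p)]))
  to <- unlist(lapply(paths, function(p) p[-1L]))
  df <- unique(data.frame(from = pmin(from, to), to = pmax(from, to),
                          stringsAsFactors = FALSE))
  net_df <- network_edges(network)
  idx <- match(paste(df$from, df$to, sep = "|"),
               paste(net_df$from, net_df$to, sep = "|"))
  df$observation_count <- ifelse(is.na(idx), 1L, net_df$observation_count[idx])
  df$provenance <- ifelse(is.na(idx), "observed", net_df$provenance[idx])
  interaction_network(df)
}

#' @export
print.petal <- function(x, ...) {
  cat("petal ->", x$candidate, ":", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges,", sum(x$paths$kept), "of",
      nrow(x$paths), "paths kept\n")
  invisible(x)
}

#' Build the blossom of a driver gene
#'
#' For each candidate gene: compute the diameter bound on the raw network
#' (falling back to the imputed network only on disconnection), enumerate
#' all simple paths within the bound on the imputed network, score and
#' filter them, and merge the survivors into a petal. Candidates with an
#' infinite bound or an empty petal are omitted. Per-candidate results are
#' independent and derived from per-candidate seeds, so the blossom does
#' not depend on candidate processing order.
#'
#' @param driver driver gene c_a.
#' @param candidates character vector of candidate genes.
#' @param G raw `igraph` network.
#' @param G_imputed refined + imputed `igraph` network (G'').
#' @param coexpr_map a `coexpression_map`.
#' @param rules rule table from [mine_rules()].
#' @param leaf_annotations leaf-restricted annotation map.
#' @param gamma,p_threshold,n_null,seed as in [build_petal()].
#' @param max_bound safety cap on the path-search bound (exhaustive search
#'   is exponential in the bound; candidates whose bound exceeds the cap
#'   are skipped with a warning).
#' @return object of class `blossom`: list with `driver` and `petals`
#'   (named list of non-empty `petal` objects, lexicographic candidate
#'   order).
#' @export
build_blossom <- function(driver, candidates, G, G_imputed, coexpr_map,
                          rules, leaf_annotations, gamma = 0.6,
                          p_threshold = 0.05, n_null = 1000L, seed = 1L,
                          max_bound = 8L) {
  if (!driver %in% igraph::V(G)$name) stop("driver not in network: ", driver)
  candidates <- sort(unique(setdiff(candidates, driver)))
  petals <- list()
  for (ci in candidates) {
    if (!ci %in% igraph::V(G)$name) next
    d <- diameter_bound(G, G_imputed, driver, ci)
    if (is.infinite(d) || d < 1L) next
    if (d > max_bound) {
      warning("candidate ", ci, " skipped: bound ", d, " exceeds max_bound")
      next
    }
    paths <- all_paths_dfs(G_imputed, driver, ci, d)
    if (!length(paths)) next
    petal <- build_petal(ci, paths, coexpr_map, rules, leaf_annotations,
                         G_imputed, gamma = gamma, p_threshold = p_threshold,
                         n_null = n_null, seed = derive_seed(seed, match(ci, candidates)))
    if (igraph::vcount(petal$graph) > 0L) petals[[ci]] <- petal
  }
  structure(list(driver = driver, petals = petals), class = "blossom")
}

#' @export
print.blossom <- function(x, ...) {
  cat("blossom of", x$driver, "with", length(x$petals), "petal(s):",
      paste(names(x$petals), collapse = ", "), "\n")
  invisible(x)
}

# deterministic 32-bit sub-seed from a master seed and an index or name
derive_seed <- function(seed, index) {
  if (is.character(index)) {
    h <- 0
    for (ch in utf8ToInt(index)) h <- (h * 31 + ch) %% 2147483647
    index <- h
  }
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(index) * 40503) %% 2147483647)
}
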