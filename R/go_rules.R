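#' Restrict annotations to GO leaf terms
#'
#' For each protein, keeps only the most specific terms: a term is dropped
#' when one of its descendants in the GO graph also annotates the same
#' protein. The restriction is per protein (a term may be a leaf for one
#' protein and redundant for another) and idempotent.
#'
#' @param annotations named list gene -> GO term IDs.
#' @param go_graph a `go_graph`.
#' @return named list gene -> leaf term IDs.
#' @export
leaf_annotations <- function(annotations, go_graph) {
  all_terms <- unique(unlist(annotations, use.names = FALSE))
  unknown <- setdiff(all_terms, go_graph$terms)
  if (length(unknown)) stop("annotation term(s) not in GO graph: ",
                            paste(utils::head(unknown, 3), collapse = ", "))
  anc <- term_ancestors(go_graph)
  lapply(annotations, function(terms) {
    terms <- unique(terms)
    if (length(terms) < 2L) return(terms)
    covered <- unique(unlist(anc[terms], use.names = FALSE))
    sort(setdiff(terms, covered))
  })
}

# term -> all (proper) ancestors via is_a/part_of closure
term_ancestors <- function(go_graph) {
  parents <- split(go_graph$parents$parent, go_graph$parents$child)
  anc <- stats::setNames(vector("list", length(go_graph$terms)), go_graph$terms)
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    p <- parents[[t]]
    res <- if (is.null(p)) character(0) else {
      unique(c(p, unlist(lapply(p, get_anc), use.names = FALSE)))
    }
    anc[[t]] <<- res
    res
  }
  for (t in go_graph$terms) get_anc(t)
  anc
}

rule_key <- function(ta, tb) paste(pmin(ta, tb), pmax(ta, tb), sep = "|")

#' Mine GO association rules from known pathways
#'
#' An association rule is an unordered pair of GO leaf terms observed on a
#' pair of proteins that are both members of the same known pathway and
#' adjacent in the interaction network. The support of a rule is the
#' number of distinct such protein pairs exhibiting its term pair; rules
#' with support >= `min_support` are returned.
#'
#' @param pathways named list of gene sets (known pathways).
#' @param leaf_annotations leaf-restricted annotation map from
#'   [leaf_annotations()].
#' @param network `igraph` interaction network defining adjacency.
#' @param min_support minimum support count (>= 1).
#' @return data.frame with columns `termA`, `termB` (termA <= termB) and
#'   `support`, sorted by decreasing support.
#' @export
mine_rules <- function(pathways, leaf_annotations, network, min_support = 1L) {
  stopifnot(min_support >= 1L)
  empty <- data.frame(termA = character(), termB = character(),
                      support = integer(), stringsAsFactors = FALSE)
  if (!length(pathways)) return(empty)
  ekeys <- edge_keys(network)
  seen <- new.env(parent = emptyenv())  # rule key -> set of protein-pair keys
  for (pw in pathways) {
    pw <- intersect(unique(pw), igraph::V(network)$name)
    if (length(pw) < 2L) next
    pairs <- utils::combn(sort(pw), 2L)
    for (k in seq_len(ncol(pairs))) {
      u <- pairs[1L, k]; v <- pairs[2L, k]
      if (!paste(u, v, sep = "|") %in% ekeys) next
      tu <- leaf_annotations[[u]]; tv <- leaf_annotations[[v]]
      if (!length(tu) || !length(tv)) next
      grid <- expand.grid(tu, tv, stringsAsFactors = FALSE)
      rk <- unique(rule_key(grid[[1]], grid[[2]]))
      ppair <- paste(u, v, sep = "|")
      for (key in rk) {
        seen[[key]] <- unique(c(seen[[key]], ppair))
      }
    }
  }
  keys <- ls(seen)
  if (!length(keys)) return(empty)
  support <- vapply(keys, function(k) length(seen[[k]]), 0L)
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(termA = vapply(parts, `[[`, "", 1L),
                    termB = vapply(parts, `[[`, "", 2L),
                    support = support, stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(-out$support, out$termA, out$termB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# precompiled rule matcher: returns function(path) -> rule count, using a
# gene x term membership matrix so per-path scoring is allocation-light
rule_matcher <- function(rules, leaf_annotations) {
  if (nrow(rules) == 0L || !length(leaf_annotations)) {
    return(function(path) 0L)
  }
  genes <- names(leaf_annotations)
  terms <- unique(c(rules$termA, rules$termB,
                    unlist(leaf_annotations, use.names = FALSE)))
  M <- matrix(FALSE, length(genes), length(terms),
              dimnames = list(genes, terms))
  for (g in genes) M[g, leaf_annotations[[g]]] <- TRUE
  ia <- match(rules$termA, terms)
  ib <- match(rules$termB, terms)
  function(path) {
    idx <- match(path, genes)
    total <- 0L
    for (k in seq_len(length(path) - 1L)) {
      u <- idx[k]; v <- idx[k + 1L]
      if (is.na(u) || is.na(v)) next
      total <- total + sum((M[u, ia] & M[v, ib]) | (M[u, ib] & M[v, ia]))
    }
    total
  }
}

#' Count association-rule occurrences along a path
#'
#' Sums, over the consecutive protein pairs (u, v) of a simple path, the
#' number of rules whose two terms annotate u and v (in either
#' orientation). Each rule is counted at most once per edge, so the count
#' is invariant under path reversal.
#'
#' @param path character vector of node names (a simple path).
#' @param rules rule table from [mine_rules()].
#' @param leaf_annotations leaf-restricted annotation map.
#' @return integer rule count.
#' @export
path_rule_count <- function(path, rules, leaf_annotations) {
  if (length(path) < 2L || nrow(rules) == 0L) return(0L)
  as.integer(rule_matcher(rules, leaf_annotations)(path))
}

# sample one simple path with exactly `len` edges by a random walk that
# restarts when it would revisit a node; NULL on failure
random_simple_path <- function(adj, vnames, len) {
  cur <- sample(vnames, 1L)
  path <- cur
  for (step in seq_len(len)) {
    nb <- setdiff(adj[[cur]], path)
    if (!length(nb)) return(NULL)
    cur <- if (length(nb) == 1L) nb else sample(nb, 1L)
    path <- c(path, cur)
  }
  path
}

#' Empirical significance of a path's rule count
#'
#' Tests the observed rule count of a path against the null hypothesis
#' that rule occurrence is uniform across simple paths of the network:
#' the null sample is the rule counts of `n_null` random simple paths
#' with the same edge count, drawn by random walks that restart when they
#' would revisit a node. The p-value uses add-one smoothing,
#' p = (1 + #\{null >= observed\}) / (1 + n_null), so it is never 0.
#'
#' @param path character vector of node names.
#' @param rules rule table from [mine_rules()].
#' @param leaf_annotations leaf-restricted annotation map.
#' @param network `igraph` network to sample null paths from.
#' @param n_null number of null paths (default 1000, >= 100 recommended).
#' @param seed integer seed.
#' @return p-value in (0, 1\].
#' @export
path_significance <- function(path, rules, leaf_annotations, network,
                              n_null = 1000L, seed = 1L) {
  len <- length(path) - 1L
  stopifnot(len >= 1L)
  matcher <- rule_matcher(rules, leaf_annotations)
  adj <- adjacency_list(network)
  null_counts <- null_rule_counts(len, matcher, adj, n_null, seed)
  (1 + sum(null_counts >= matcher(path))) / (1 + length(null_counts))
}

adjacency_list <- function(network) {
  vnames <- igraph::V(network)$name
  adj <- lapply(igraph::adjacent_vertices(network, vnames), names)
  names(adj) <- vnames
  adj
}

# null sample of rule counts over random simple paths of a given length
null_rule_counts <- function(len, matcher, adj, n_null, seed) {
  vnames <- names(adj)
  withr::with_seed(seed, {
    null_counts <- integer(0)
    tries <- 0L
    max_tries <- 100L * n_null
    while (length(null_counts) < n_null && tries < max_tries) {
      tries <- tries + 1L
      p <- random_simple_path(adj, vnames, len)
      if (!is.null(p)) null_counts <- c(null_counts, matcher(p))
    }
    if (!length(null_counts)) {
      stop("no simple path of length ", len, " found in network")
    }
    if (length(null_counts) < n_null) {
      warning("only ", length(null_counts), " of ", n_null,
              " null paths sampled")
    }
    null_counts
  })
}
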