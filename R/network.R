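#' Construct an interaction network
#'
#' Builds the undirected protein-protein interaction graph used throughout
#' the pipeline. Edges are unordered gene pairs with two attributes: an
#' `observation_count` (how many times the interaction was reported) and a
#' `provenance` flag, `"observed"` for experimentally reported edges and
#' `"imputed"` for edges inferred from protein-family evidence.
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `observation_count` (default 1) and `provenance` (default "observed").
#'   Repeated rows for the same unordered pair have their observation
#'   counts summed; self-loops are dropped with a warning.
#' @param nodes optional character vector of node names to include even if
#'   isolated (the vertex set V is kept fixed across filtering).
#' @return an undirected `igraph` object with vertex attribute `name` and
#'   edge attributes `observation_count`, `provenance`.
#' @export
interaction_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (!is.null(nodes) && length(nodes) > 0L) {
      g <- igraph::add_vertices(g, length(nodes), name = unique(as.character(nodes)))
    }
    return(g)
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  count <- if ("observation_count" %in% names(edges)) {
    as.integer(edges$observation_count)
  } else {
    rep(1L, nrow(edges))
  }
  prov <- if ("provenance" %in% names(edges)) {
    as.character(edges$provenance)
  } else {
    rep("observed", nrow(edges))
  }
  if (any(bad <- !prov %in% c("observed", "imputed"))) {
    stop("unknown provenance value(s): ", paste(unique(prov[bad]), collapse = ", "))
  }
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]
    count <- count[!loops]; prov <- prov[!loops]
  }
  # canonical unordered key so {a,b} == {b,a}
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  agg_count <- tapply(count, key, sum)
  agg_prov <- tapply(prov, key, function(p) if (any(p == "observed")) "observed" else "imputed")
  keys <- names(agg_count)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  ea <- vapply(parts, `[[`, "", 1L)
  eb <- vapply(parts, `[[`, "", 2L)
  cnt <- as.integer(agg_count[keys])
  pv <- as.character(agg_prov[keys])
  cnt[pv == "imputed"] <- 0L  # imputed edges carry no observation evidence
  vnames <- unique(c(ea, eb, as.character(nodes)))
  g <- igraph::make_empty_graph(n = length(vnames), directed = FALSE)
  igraph::V(g)$name <- vnames
  g <- igraph::add_edges(g, rbind(match(ea, vnames), match(eb, vnames)))
  igraph::E(g)$observation_count <- cnt
  igraph::E(g)$provenance <- pv
  g
}

#' Extract the edge table of an interaction network
#'
#' @param network an `igraph` interaction network.
#' @return data.frame with columns `from`, `to`, `observation_count`,
#'   `provenance`, one row per edge, endpoints in canonical (sorted) order.
#' @export
network_edges <- function(network) {
  if (igraph::ecount(network) == 0L) {
    return(data.frame(from = character(), to = character(),
                      observation_count = integer(), provenance = character(),
                      stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(network, names = TRUE)
  cnt <- igraph::E(network)$observation_count
  if (is.null(cnt)) cnt <- rep(1L, nrow(el))
  prov <- igraph::E(network)$provenance
  if (is.null(prov)) prov <- rep("observed", nrow(el))
  df <- data.frame(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
                   observation_count = as.integer(cnt), provenance = prov,
                   stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}

# canonical "a|b" edge keys (internal)
edge_keys <- function(network) {
  df <- network_edges(network)
  paste(df$from, df$to, sep = "|")
}
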