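#' Small-world clustering coefficient of a node
#'
#' Fraction of a node's neighbor pairs that are themselves connected,
#' i.e. edges among neighbors / (k(k-1)/2) for degree k. Nodes of degree
#' < 2 get coefficient 0.
#'
#' @param network `igraph` interaction network.
#' @param node node name.
#' @return numeric in \[0, 1\].
#' @export
clustering_coefficient <- function(network, node) {
  if (!node %in% igraph::V(network)$name) stop("node not in network: ", node)
  nb <- igraph::neighbors(network, node)
  k <- length(nb)
  if (k < 2L) return(0)
  sub <- igraph::induced_subgraph(network, nb)
  igraph::ecount(sub) / (k * (k - 1) / 2)
}

#' Per-edge reliability features
#'
#' Computes, for every edge of the network, the four features of the
#' interaction-reliability model: observation count, Pearson coexpression
#' of the two endpoint genes, mean endpoint clustering coefficient, and a
#' subcellular-localization compartment overlap (Jaccard index).
#' Missing data degrades to neutral defaults: coexpression 0 when either
#' gene is absent from the array (or constant), localization 0 when either
#' annotation set is empty.
#'
#' @param network `igraph` interaction network.
#' @param expression optional `expression_bundle` for coexpression.
#' @param localization_map optional named list gene -> compartment tokens.
#' @return data.frame with columns `from`, `to`, `obs_count`, `coexpr`,
#'   `clustering`, `localization`, one row per edge.
#' @export
compute_edge_features <- function(network, expression = NULL,
                                  localization_map = NULL) {
  df <- network_edges(network)
  n <- nrow(df)
  cc <- vapply(igraph::V(network)$name,
               function(v) clustering_coefficient(network, v), 0)
  clus <- (cc[df$from] + cc[df$to]) / 2
  coex <- numeric(n)
  if (!is.null(expression) && n > 0L) {
    vals <- expression$values
    sds <- apply(vals, 1L, stats::sd)
    ok <- function(g) g %in% rownames(vals) && isTRUE(sds[g] > 0)
    for (i in seq_len(n)) {
      a <- df$from[i]; b <- df$to[i]
      if (ok(a) && ok(b)) coex[i] <- stats::cor(vals[a, ], vals[b, ])
    }
  }
  loc <- numeric(n)
  if (!is.null(localization_map) && n > 0L) {
    for (i in seq_len(n)) {
      sa <- localization_map[[df$from[i]]]
      sb <- localization_map[[df$to[i]]]
      if (length(sa) && length(sb)) {
        loc[i] <- length(intersect(sa, sb)) / length(union(sa, sb))
      }
    }
  }
  data.frame(from = df$from, to = df$to,
             obs_count = df$observation_count,
             coexpr = coex, clustering = unname(clus), localization = loc,
             stringsAsFactors = FALSE)
}

feature_cols <- c("obs_count", "coexpr", "clustering", "localization")

feature_rows <- function(features, edges) {
  key <- paste(features$from, features$to, sep = "|")
  idx <- match(edges, key)
  if (anyNA(idx)) stop("edge(s) missing from feature table: ",
                       paste(utils::head(edges[is.na(idx)], 3), collapse = ", "))
  features[idx, feature_cols, drop = FALSE]
}

#' Train the interaction-reliability model
#'
#' Fits a logistic regression of edge truth on the four edge features,
#' using labeled positive (trusted) and negative (random) edges. The
#' probability cutoff separating reliable from unreliable edges is chosen
#' by repeated 80/20 train/test splits: on each repeat the test-set
#' threshold maximizing Youden's J (sensitivity + specificity - 1) is
#' recorded, and the final cutoff is the mean over repeats. The reported
#' coefficients come from a fit on all labeled edges.
#'
#' @param features feature table from [compute_edge_features()].
#' @param positives,negatives character vectors of canonical edge keys
#'   (`"a|b"`, endpoints sorted), disjoint, each of length >= 2.
#' @param n_repeats number of split repeats (default 100).
#' @param seed integer seed; results are deterministic given it.
#' @return object of class `reliability_model`: list with `coefficients`
#'   (intercept + 4 features), `cutoff`, `n_repeats`, `seed`, and
#'   `holdout` (per-repeat test accuracy and AUC).
#' @export
train_reliability_model <- function(features, positives, negatives,
                                    n_repeats = 100L, seed = 1L) {
  if (length(intersect(positives, negatives)))
    stop("positives and negatives overlap")
  if (length(positives) < 2L || length(negatives) < 2L)
    stop("need >= 2 labeled edges per class")
  X <- feature_rows(features, c(positives, negatives))
  y <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
  dat <- cbind(y = y, X)
  full <- suppressWarnings(
    stats::glm(y ~ obs_count + coexpr + clustering + localization,
               data = dat, family = stats::binomial()))
  n <- nrow(dat)
  withr::with_seed(seed, {
    cutoffs <- acc <- auc <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      test <- sample.int(n, max(2L, round(0.2 * n)))
      # keep both classes in the training fold
      while (length(unique(dat$y[-test])) < 2L) test <- sample.int(n, max(2L, round(0.2 * n)))
      fit <- suppressWarnings(
        stats::glm(y ~ obs_count + coexpr + clustering + localization,
                   data = dat[-test, ], family = stats::binomial()))
      p <- suppressWarnings(
        stats::predict(fit, newdata = dat[test, ], type = "response"))
      yt <- dat$y[test]
      cutoffs[r] <- youden_cutoff(p, yt)
      acc[r] <- mean((p >= cutoffs[r]) == (yt == 1L))
      auc[r] <- rank_auc(p, yt)
    }
    structure(list(coefficients = stats::coef(full),
                   cutoff = mean(cutoffs),
                   n_repeats = n_repeats, seed = seed,
                   holdout = data.frame(accuracy = acc, auc = auc)),
              class = "reliability_model")
  })
}

# threshold maximizing Youden's J on held-out probabilities; midpoint
# between adjacent candidate probabilities, clamped inside (0,1)
youden_cutoff <- function(p, y) {
  cand <- sort(unique(c(0, p, 1)))
  thr <- (cand[-1L] + cand[-length(cand)]) / 2
  j <- vapply(thr, function(t) {
    sens <- if (any(y == 1L)) mean(p[y == 1L] >= t) else 0
    spec <- if (any(y == 0L)) mean(p[y == 0L] < t) else 0
    sens + spec - 1
  }, 0)
  t <- thr[which.max(j)]
  min(max(t, 1e-6), 1 - 1e-6)
}

# Mann-Whitney AUC from scores and 0/1 labels
rank_auc <- function(score, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predict per-edge reliability probabilities
#'
#' @param model a `reliability_model`.
#' @param features feature table covering the edges of interest.
#' @return numeric vector of probabilities aligned with `features` rows.
#' @export
predict_reliability <- function(model, features) {
  X <- as.matrix(cbind(1, features[, feature_cols, drop = FALSE]))
  coefs <- model$coefficients
  coefs[is.na(coefs)] <- 0  # rank-deficient fits drop constant features
  eta <- drop(X %*% coefs)
  1 / (1 + exp(-eta))
}

#' Filter a network to its reliable edges (G -> G')
#'
#' Keeps exactly the edges whose predicted reliability probability is at
#' least the model cutoff. The vertex set is unchanged: nodes whose edges
#' are all removed stay in the graph as isolated vertices.
#'
#' @param network `igraph` interaction network (G).
#' @param model `reliability_model`, or a list with a `cutoff` and optional
#'   `probabilities` override.
#' @param features feature table covering every edge of `network`.
#' @param cutoff optional cutoff override (config escape hatch; the
#'   effective cutoff of the original analysis depends on its data
#'   snapshot and is not recoverable).
#' @return list with `network` (G', same vertices, surviving edges) and
#'   `removed` (data.frame of removed edges F with their probabilities).
#' @export
filter_network <- function(network, model, features, cutoff = NULL) {
  df <- network_edges(network)
  feats <- feature_rows(features, paste(df$from, df$to, sep = "|"))
  prob <- predict_reliability(model, feats)
  cut <- if (is.null(cutoff)) model$cutoff else cutoff
  keep <- prob >= cut
  gprime <- interaction_network(df[keep, , drop = FALSE],
                                nodes = igraph::V(network)$name)
  removed <- cbind(df[!keep, , drop = FALSE], probability = prob[!keep])
  rownames(removed) <- NULL
  list(network = gprime, removed = removed)
}

#' Impute likely false-negative edges from family evidence (G' -> G'')
#'
#' Two protein families are said to interact when at least one observed
#' edge of the filtered network joins a member of one to a member of the
#' other. For every non-adjacent protein pair (a, b) such that some family
#' of a interacts with some family of b, an edge is added with provenance
#' `"imputed"` and observation count 0. Family evidence is taken from
#' observed edges only, so imputation is idempotent.
#'
#' @param filtered_network `igraph` network (G').
#' @param family_map named list gene -> family IDs; unmapped proteins never
#'   receive imputed edges.
#' @return `igraph` network G'' containing all edges of G' plus the imputed
#'   set H.
#' @export
impute_edges <- function(filtered_network, family_map) {
  df <- network_edges(filtered_network)
  vnames <- igraph::V(filtered_network)$name
  obs <- df[df$provenance == "observed", , drop = FALSE]
  if (nrow(obs) == 0L || length(family_map) == 0L) return(filtered_network)
  # interacting family pairs, from observed edges
  fam_pairs <- character(0)
  for (i in seq_len(nrow(obs))) {
    fa <- family_map[[obs$from[i]]]
    fb <- family_map[[obs$to[i]]]
    if (length(fa) && length(fb)) {
      grid <- expand.grid(fa, fb, stringsAsFactors = FALSE)
      fam_pairs <- c(fam_pairs,
                     paste(pmin(grid[[1]], grid[[2]]),
                           pmax(grid[[1]], grid[[2]]), sep = "|"))
    }
  }
  fam_pairs <- unique(fam_pairs)
  if (!length(fam_pairs)) return(filtered_network)
  members <- split(rep(names(family_map), lengths(family_map)),
                   unlist(family_map, use.names = FALSE))
  members <- lapply(members, function(x) intersect(unique(x), vnames))
  existing <- edge_keys(filtered_network)
  new_from <- character(0); new_to <- character(0)
  for (fp in fam_pairs) {
    fams <- strsplit(fp, "|", fixed = TRUE)[[1L]]
    ma <- members[[fams[1L]]]; mb <- members[[fams[2L]]]
    if (!length(ma) || !length(mb)) next
    grid <- expand.grid(ma, mb, stringsAsFactors = FALSE)
    a <- pmin(grid[[1]], grid[[2]]); b <- pmax(grid[[1]], grid[[2]])
    ok <- a != b & !paste(a, b, sep = "|") %in% existing
    new_from <- c(new_from, a[ok]); new_to <- c(new_to, b[ok])
  }
  if (!length(new_from)) return(filtered_network)
  add <- unique(data.frame(from = new_from, to = new_to,
                           observation_count = 0L, provenance = "imputed",
                           stringsAsFactors = FALSE))
  interaction_network(rbind(df, add), nodes = vnames)
}
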