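#' All-pairs Pearson coexpression map
#'
#' Pearson correlation across all samples (wild-type and mutant pooled;
#' both conditions contribute to the correlation estimate). Genes with
#' zero variance get correlation 0 against every partner (and against
#' themselves), rather than NaN, so downstream vectorization never
#' propagates missing values; they are flagged in the result.
#'
#' @param expression an `expression_bundle` with >= 3 samples.
#' @param gene_subset optional character vector restricting the gene
#'   universe S.
#' @return object of class `coexpression_map`: list with `genes`, the
#'   correlation `matrix` (genes x genes), and `constant` (flagged
#'   zero-variance genes).
#' @export
pearson_map <- function(expression, gene_subset = NULL) {
  vals <- expression$values
  if (ncol(vals) < 3L) stop("need >= 3 samples for coexpression")
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(vals))
    if (length(missing)) stop("gene(s) not on array: ",
                              paste(utils::head(missing, 3), collapse = ", "))
    vals <- vals[gene_subset, , drop = FALSE]
  }
  sds <- apply(vals, 1L, stats::sd)
  constant <- rownames(vals)[sds == 0]
  r <- suppressWarnings(stats::cor(t(vals)))
  r[is.na(r)] <- 0
  if (length(constant)) r[constant, ] <- r[, constant] <- 0
  structure(list(genes = rownames(vals), matrix = r, constant = constant),
            class = "coexpression_map")
}

#' Look up pairwise coexpression values
#'
#' @param map a `coexpression_map`.
#' @param i,j gene names (vectors recycle as in matrix indexing).
#' @return numeric vector of correlations.
#' @export
coexpr <- function(map, i, j) {
  map$matrix[cbind(i, j)]
}

#' Per-gene activity from differential expression
#'
#' The activity of a gene is its scaled absolute differential expression:
#' a Welch-style t statistic between mutant and wild-type samples,
#' t = (mean_MT - mean_WT) / sqrt(var_MT/n_MT + var_WT/n_WT)
#' (unbiased sample variances), scaled by the cohort maximum so that
#' alpha = |t| / max |t| lies in \[0, 1\] and the most differentially
#' expressed gene has activity 1. A gene constant in both groups with
#' equal means gets t = 0 (not NaN); if every t is 0, all activities are 0.
#'
#' @param expression an `expression_bundle` with >= 2 samples per group.
#' @return data.frame with rownames = genes and columns `t`, `alpha`.
#' @export
activity <- function(expression) {
  grp <- expression$group
  n_mt <- sum(grp == "MT"); n_wt <- sum(grp == "WT")
  if (n_mt < 2L || n_wt < 2L) stop("need >= 2 samples in each of WT and MT")
  vals <- expression$values
  mt <- vals[, grp == "MT", drop = FALSE]
  wt <- vals[, grp == "WT", drop = FALSE]
  mu_mt <- rowMeans(mt); mu_wt <- rowMeans(wt)
  var_mt <- apply(mt, 1L, stats::var); var_wt <- apply(wt, 1L, stats::var)
  se <- sqrt(var_mt / n_mt + var_wt / n_wt)
  t <- ifelse(se == 0, ifelse(mu_mt == mu_wt, 0, Inf * sign(mu_mt - mu_wt)),
              (mu_mt - mu_wt) / se)
  # genes with zero variance but shifted means have infinite t; they get
  # activity 1 and are excluded from the scaling maximum
  finite_max <- suppressWarnings(max(abs(t[is.finite(t)]), 0))
  alpha <- if (finite_max == 0) {
    as.numeric(is.infinite(t))
  } else {
    pmin(ifelse(is.infinite(t), 1, abs(t) / finite_max), 1)
  }
  data.frame(t = t, alpha = alpha, row.names = rownames(vals))
}

#' Activity-weighted ("active") coexpression matrix R'(P, X)
#'
#' Each entry is r'(i, x) = alpha_i * r(i, x): the Pearson correlation of
#' petal node i with gene x, weighted by i's activity so that coexpression
#' only counts when the source gene is differentially expressed.
#'
#' @param activity activity table from [activity()].
#' @param coexpr_map a `coexpression_map` whose universe contains the
#'   target set.
#' @param petal_nodes character vector of petal gene IDs (rows). Nodes
#'   absent from the coexpression universe are dropped with a warning.
#' @param target_set character vector of gene IDs (columns), a subset of
#'   the coexpression universe.
#' @return numeric matrix, rows = surviving petal nodes, columns =
#'   `target_set`.
#' @export
active_coexpression <- function(activity, coexpr_map, petal_nodes, target_set) {
  missing <- setdiff(target_set, coexpr_map$genes)
  if (length(missing)) stop("target gene(s) not in coexpression universe: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  keep <- petal_nodes %in% coexpr_map$genes & petal_nodes %in% rownames(activity)
  if (any(!keep)) warning("dropping petal node(s) absent from array: ",
                          paste(petal_nodes[!keep], collapse = ", "))
  petal_nodes <- petal_nodes[keep]
  if (!length(petal_nodes)) stop("no petal node present on the array")
  r <- coexpr_map$matrix[petal_nodes, target_set, drop = FALSE]
  alpha <- activity[petal_nodes, "alpha"]
  r * alpha
}

#' Vectorize an active-coexpression matrix, excluding self pairs
#'
#' @param rmat matrix from [active_coexpression()].
#' @return numeric vector of entries whose row gene differs from the
#'   column gene.
#' @export
vec_active <- function(rmat) {
  self <- outer(rownames(rmat), colnames(rmat), `==`)
  rmat[!self]
}
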