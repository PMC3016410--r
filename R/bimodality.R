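#' Bimodality statistic beta
#'
#' beta = -1/2 (E\[x^2 of sample\] - E\[x^2 of background\]): minus half
#' the difference between the second moments of the two active-coexpression
#' distributions. Negative beta means the sample (petal-to-target) values
#' have heavier two-sided tails than the background — coordinated positive
#' and negative coexpression with the targets; positive beta means the
#' sample is more concentrated at zero than the background.
#'
#' @param sample_values numeric vector, vec(R'(P, D)).
#' @param background_values numeric vector, vec(R'(P, S)).
#' @return numeric beta.
#' @export
beta <- function(sample_values, background_values) {
  if (!length(sample_values) || !length(background_values))
    stop("empty input to beta")
  if (anyNA(sample_values) || anyNA(background_values) ||
      any(!is.finite(c(sample_values, background_values))))
    stop("non-finite value in beta input")
  -0.5 * (mean(sample_values^2) - mean(background_values^2))
}

#' Torque-formulation oracle for beta
#'
#' Computes beta through its center-of-mass / torque formulation: the
#' integral of x * DeltaF(x) over the real line, where DeltaF is the
#' difference between the sample and background empirical CDFs. The
#' normalizing denominators of the two moment arms cancel, leaving a plain
#' integral, evaluated here by the trapezoidal rule on a regular grid
#' spanning both supports. Exists as an independent cross-check of
#' [beta()]; the two agree up to grid resolution.
#'
#' @param sample_values,background_values as in [beta()].
#' @param n_grid number of grid points (>= 1000).
#' @return numeric beta approximation.
#' @export
beta_torque_oracle <- function(sample_values, background_values,
                               n_grid = 1e5) {
  if (!length(sample_values) || !length(background_values))
    stop("empty input to beta_torque_oracle")
  if (anyNA(sample_values) || anyNA(background_values) ||
      any(!is.finite(c(sample_values, background_values))))
    stop("non-finite value in beta_torque_oracle input")
  stopifnot(n_grid >= 1000)
  lo <- min(sample_values, background_values)
  hi <- max(sample_values, background_values)
  if (lo == hi) return(0)
  pad <- (hi - lo) * 1e-9
  x <- seq(lo - pad, hi + pad, length.out = n_grid)
  Fd <- stats::ecdf(sample_values)(x)   # right-continuous, P(X <= x)
  Fs <- stats::ecdf(background_values)(x)
  dF <- Fd - Fs
  y <- x * dF
  h <- x[2L] - x[1L]
  sum((y[-1L] + y[-length(y)]) / 2) * h
}

#' Permutation test of petal-target bimodality
#'
#' The observed beta compares vec(R'(P, D)) (petal to proteomic targets)
#' against vec(R'(P, S)) (petal to all genes on the array, the background;
#' D is a subset of S and is not excluded). The null draws `n_perm` random
#' target sets of size |D| uniformly without replacement from S and
#' recomputes beta for each. The p-value is the lower-tail rank,
#' p = #\{beta_rand < beta_P\} / n_perm (more-negative beta = stronger
#' bimodal coexpression); with `smoothed = TRUE` an add-one-smoothed
#' variant (1 + #) / (1 + n_perm) is returned instead, and with
#' `two_sided = TRUE` the tail is taken on |beta|. Self pairs (a petal
#' gene correlated with itself) are excluded from both vectors.
#'
#' @param petal_nodes character vector of petal genes P.
#' @param targets character vector of target genes D (subset of the
#'   universe, with |D| < |S|).
#' @param activity activity table from [activity()].
#' @param coexpr_map a `coexpression_map` whose universe is S.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param smoothed use add-one smoothing (default FALSE: the raw rank,
#'   which can be exactly 0).
#' @param two_sided rank on |beta| instead of the lower tail.
#' @return object of class `bimodality_result`: list with `beta`, `null`
#'   (the beta_rand sample), `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(petal_nodes, targets, activity, coexpr_map,
                             n_perm = 10000L, seed = 1L, smoothed = FALSE,
                             two_sided = FALSE) {
  universe <- coexpr_map$genes
  missing <- setdiff(targets, universe)
  if (length(missing)) stop("target(s) not in gene universe: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  if (length(targets) >= length(universe))
    stop("|D| must be smaller than |S|")
  rmat <- active_coexpression(activity, coexpr_map, petal_nodes, universe)
  # square once; mask self pairs so means ignore them
  sq <- rmat^2
  self <- outer(rownames(sq), colnames(sq), `==`)
  sq[self] <- NA
  bg_mean <- mean(sq, na.rm = TRUE)
  beta_of <- function(cols) {
    -0.5 * (mean(sq[, cols, drop = FALSE], na.rm = TRUE) - bg_mean)
  }
  beta_obs <- beta_of(targets)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      beta_of(sample(universe, length(targets)))
    }, 0)
  })
  stat_obs <- if (two_sided) -abs(beta_obs) else beta_obs
  stat_null <- if (two_sided) -abs(null) else null
  p <- if (smoothed) {
    (1 + sum(stat_null < stat_obs)) / (1 + n_perm)
  } else {
    sum(stat_null < stat_obs) / n_perm
  }
  structure(list(beta = beta_obs, null = null, p = p,
                 n_perm = n_perm, seed = seed),
            class = "bimodality_result")
}

#' @export
print.bimodality_result <- function(x, ...) {
  cat("beta =", format(x$beta, digits = 4), ", p =", format(x$p, digits = 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Rank the petals of a blossom against a proteomic target list
#'
#' Runs [permutation_test()] for every petal (with independent seeds
#' derived from the master seed and the candidate name) and orders the
#' results by ascending p-value, ties broken by beta then candidate name.
#' A Benjamini-Hochberg adjusted p-value column is appended as
#' supplementary output.
#'
#' @param blossom a `blossom`.
#' @param targets character vector of target genes D.
#' @param activity activity table from [activity()].
#' @param coexpr_map a `coexpression_map`.
#' @param n_perm,seed,smoothed,two_sided as in [permutation_test()].
#' @return data.frame with columns `candidate`, `n_nodes`, `n_edges`,
#'   `beta`, `p`, `p_bh`.
#' @export
rank_petals <- function(blossom, targets, activity, coexpr_map,
                        n_perm = 10000L, seed = 1L, smoothed = FALSE,
                        two_sided = FALSE) {
  if (!length(blossom$petals)) stop("blossom has no petals to rank")
  cand <- names(blossom$petals)
  rows <- lapply(seq_along(cand), function(k) {
    petal <- blossom$petals[[k]]
    nodes <- igraph::V(petal$graph)$name
    res <- permutation_test(nodes, targets, activity, coexpr_map,
                            n_perm = n_perm,
                            seed = derive_seed(seed, cand[k]),
                            smoothed = smoothed, two_sided = two_sided)
    data.frame(candidate = cand[k],
               n_nodes = igraph::vcount(petal$graph),
               n_edges = igraph::ecount(petal$graph),
               beta = res$beta, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$beta, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  out
}
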