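#' Specification of a synthetic fixture
#'
#' Describes a self-contained synthetic world with known ground truth:
#' a scale-free (or Erdos-Renyi) interaction network with one driver gene
#' and several candidate genes, each connected to the driver by a planted
#' simple path; a latent-factor expression model in which the genes of
#' each planted path load on a petal factor coupled to a shared driver
#' factor; proteomic targets of which a chosen fraction truly co-express
#' (with alternating sign, producing the two coexpression modes) with the
#' planted petal; differential expression injected as a mutant-vs-wild-type
#' mean shift on petal genes; GO annotations and pathways constructed so
#' every planted path edge is supported by at least one mined association
#' rule; a protein-family map over background genes; and a set of planted
#' low-evidence "unreliable" edges for the reliability filter to remove.
#'
#' Defaults describe a desk-scale version of the data the method was
#' designed for: 500 genes, 8 wild-type + 8 mutant samples (two fractions
#' of four collapse to eight per condition), ~1500 interactions, 31
#' proteomic targets, 6 candidate genes with a planted path of 3 edges
#' each, and loadings chosen so planted petal-target correlations land
#' near 0.6.
#'
#' @param n_genes total gene universe size.
#' @param n_per_group samples per condition (WT and MT).
#' @param n_edges target number of background network edges.
#' @param network_model `"pa"` (preferential attachment) or `"er"`.
#' @param n_candidates number of candidate genes (one planted, rest decoys).
#' @param path_len planted path length in edges.
#' @param n_targets proteomic target count.
#' @param frac_true fraction of targets truly loading on the planted petal.
#' @param petal_loading loading of petal genes on their petal factor.
#' @param driver_coupling correlation of each petal factor with the shared
#'   driver factor.
#' @param driver_loading loading of the driver gene on the driver factor.
#' @param target_loading loading of true targets on the planted petal factor.
#' @param shift MT-vs-WT mean shift added to petal genes (expression units;
#'   with unit-variance genes and 8+8 samples, shift 1.5 gives |t| near 3).
#' @param background_shift_sd standard deviation of the small random shifts
#'   given to background genes so activity is not degenerate.
#' @param n_unreliable number of planted low-evidence edges.
#' @param n_families protein families over background genes.
#' @param seed integer seed; the fixture is a pure function of the spec.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 500L, n_per_group = 8L, n_edges = 1500L,
                         network_model = c("pa", "er"), n_candidates = 6L,
                         path_len = 3L, n_targets = 31L, frac_true = 0.5,
                         petal_loading = 0.93, driver_coupling = 0.6,
                         driver_loading = 0.95, target_loading = 0.81,
                         shift = 1.5, background_shift_sd = 0.3,
                         n_unreliable = 600L, n_families = 150L, seed = 1L) {
  network_model <- match.arg(network_model)
  spec <- list(n_genes = as.integer(n_genes),
               n_per_group = as.integer(n_per_group),
               n_edges = as.integer(n_edges), network_model = network_model,
               n_candidates = as.integer(n_candidates),
               path_len = as.integer(path_len),
               n_targets = as.integer(n_targets), frac_true = frac_true,
               petal_loading = petal_loading,
               driver_coupling = driver_coupling,
               driver_loading = driver_loading,
               target_loading = target_loading, shift = shift,
               background_shift_sd = background_shift_sd,
               n_unreliable = as.integer(n_unreliable),
               n_families = as.integer(n_families), seed = as.integer(seed))
  stopifnot(spec$n_genes > 0, spec$n_per_group >= 2, spec$n_candidates >= 1,
            spec$path_len >= 1, spec$n_targets >= 1,
            spec$frac_true >= 0, spec$frac_true <= 1,
            abs(spec$petal_loading) < 1, abs(spec$target_loading) < 1)
  n_special <- 1L + spec$n_candidates * spec$path_len
  if (spec$n_genes < n_special + spec$n_targets + 20L)
    stop("n_genes too small for the planted structure")
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic input bundle with known ground truth
#'
#' @param spec a `fixture_spec`.
#' @param dir optional directory; when given, every input is also written
#'   in its standard external format (edge list TSV, expression matrix +
#'   groups TSV, GAF, OBO, GMT, family/localization TSV, target list,
#'   trusted-edge list, ground_truth.json).
#' @return list with elements `network` (raw G including unreliable
#'   edges), `expression`, `annotations`, `go_graph`, `pathways`,
#'   `family_map`, `localization`, `targets`, `trusted_edges` (positive
#'   training edges), and `truth` (driver, candidates, planted candidate,
#'   planted paths, true targets, unreliable edge keys, model loadings).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, generate_fixture_impl(spec, dir))
}

generate_fixture_impl <- function(spec, dir) {
  driver <- "DRV1"
  candidates <- sprintf("CAND%d", seq_len(spec$n_candidates))
  mids <- lapply(seq_len(spec$n_candidates), function(c) {
    if (spec$path_len > 1L) sprintf("M%d_%d", c, seq_len(spec$path_len - 1L))
    else character(0)
  })
  paths <- lapply(seq_len(spec$n_candidates), function(c) {
    c(driver, mids[[c]], candidates[c])
  })
  names(paths) <- candidates
  special <- unique(unlist(paths))
  n_bg <- spec$n_genes - length(special)
  background <- sprintf("G%04d", seq_len(n_bg))
  genes <- c(special, background)

  ## ---- network: planted paths + background model + unreliable edges ----
  planted <- do.call(rbind, lapply(paths, function(p) {
    data.frame(from = p[-length(p)], to = p[-1L], stringsAsFactors = FALSE)
  }))
  # random edges live on background genes only: planted-path nodes carry
  # exactly the planted (and later imputed) edges, so each petal's node
  # set is unambiguous ground truth
  allowed <- background
  n_random <- max(0L, spec$n_edges - nrow(planted))
  bg_edges <- if (spec$network_model == "pa") {
    m <- max(1L, round(n_random / length(allowed)))
    g <- igraph::sample_pa(length(allowed), m = m, directed = FALSE)
    el <- igraph::as_edgelist(g)
    perm <- sample(allowed)
    data.frame(from = perm[el[, 1L]], to = perm[el[, 2L]],
               stringsAsFactors = FALSE)
  } else {
    pairs <- matrix(sample(allowed, 8L * n_random, replace = TRUE), ncol = 2L)
    pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    k <- paste(pmin(pairs[, 1L], pairs[, 2L]),
               pmax(pairs[, 1L], pairs[, 2L]), sep = "|")
    pairs <- pairs[!duplicated(k), , drop = FALSE]
    pairs <- pairs[seq_len(min(n_random, nrow(pairs))), , drop = FALSE]
    data.frame(from = pairs[, 1L], to = pairs[, 2L], stringsAsFactors = FALSE)
  }
  reliable <- unique(rbind(planted, bg_edges))
  key <- paste(pmin(reliable$from, reliable$to),
               pmax(reliable$from, reliable$to), sep = "|")
  reliable <- reliable[!duplicated(key), , drop = FALSE]
  reliable$observation_count <- 1L + stats::rpois(nrow(reliable), 3)
  # planted path edges are well-documented interactions: enough repeated
  # observations that the reliability filter keeps them
  planted_keys <- paste(pmin(planted$from, planted$to),
                        pmax(planted$from, planted$to), sep = "|")
  is_planted <- key[!duplicated(key)] %in% planted_keys
  reliable$observation_count[is_planted] <-
    4L + stats::rpois(sum(is_planted), 2)
  # planted unreliable edges: single-observation, random background pairs
  existing <- paste(pmin(reliable$from, reliable$to),
                    pmax(reliable$from, reliable$to), sep = "|")
  ua <- sample(allowed, 4L * spec$n_unreliable, replace = TRUE)
  ub <- sample(allowed, 4L * spec$n_unreliable, replace = TRUE)
  ok <- ua != ub & !paste(pmin(ua, ub), pmax(ua, ub), sep = "|") %in% existing
  uk <- !duplicated(paste(pmin(ua, ub), pmax(ua, ub), sep = "|")) & ok
  idx <- which(uk)[seq_len(min(spec$n_unreliable, sum(uk)))]
  unreliable <- data.frame(from = ua[idx], to = ub[idx],
                           observation_count = 1L, stringsAsFactors = FALSE)
  network <- interaction_network(rbind(reliable, unreliable), nodes = genes)
  unreliable_keys <- paste(pmin(unreliable$from, unreliable$to),
                           pmax(unreliable$from, unreliable$to), sep = "|")

  ## ---- expression: latent factors + group shift ----
  n_samp <- 2L * spec$n_per_group
  group <- rep(c("WT", "MT"), each = spec$n_per_group)
  gvec <- stats::rnorm(n_samp)                       # shared driver factor
  phi <- spec$driver_coupling
  fmat <- vapply(seq_len(spec$n_candidates), function(c) {
    phi * gvec + sqrt(1 - phi^2) * stats::rnorm(n_samp)
  }, numeric(n_samp))                                # petal factors
  lp <- spec$petal_loading
  vals <- matrix(stats::rnorm(length(genes) * n_samp), nrow = length(genes),
                 dimnames = list(genes, sprintf("S%02d", seq_len(n_samp))))
  vals <- vals * sqrt(1 - lp^2)                      # idiosyncratic part
  vals[driver, ] <- spec$driver_loading * gvec +
    sqrt(1 - spec$driver_loading^2) * stats::rnorm(n_samp)
  for (c in seq_len(spec$n_candidates)) {
    for (gn in setdiff(paths[[c]], driver)) {
      vals[gn, ] <- lp * fmat[, c] + sqrt(1 - lp^2) * stats::rnorm(n_samp)
    }
  }
  # background genes: unit variance noise
  bg_rows <- setdiff(genes, special)
  vals[bg_rows, ] <- matrix(stats::rnorm(length(bg_rows) * n_samp),
                            nrow = length(bg_rows))
  # proteomic targets: drawn from background; true ones load on petal 1
  targets <- sample(bg_rows, spec$n_targets)
  n_true <- round(spec$frac_true * spec$n_targets)
  true_targets <- targets[seq_len(n_true)]
  signs <- rep(c(1, -1), length.out = n_true)
  lt <- spec$target_loading
  for (j in seq_along(true_targets)) {
    vals[true_targets[j], ] <- signs[j] * lt * fmat[, 1L] +
      sqrt(1 - lt^2) * stats::rnorm(n_samp)
  }
  # differential expression: petal genes shifted in MT; background jitter
  mt <- group == "MT"
  for (gn in special) vals[gn, mt] <- vals[gn, mt] + spec$shift
  bg_shift <- stats::rnorm(length(bg_rows), 0, spec$background_shift_sd)
  vals[bg_rows, mt] <- vals[bg_rows, mt] + bg_shift
  expression <- expression_bundle(vals, group)

  ## ---- GO graph, annotations, pathways ----
  sig_leaves <- sprintf("GO:%07d", 100 + seq_len(spec$path_len + 1L))
  bg_leaves <- sprintf("GO:%07d", 1000 + seq_len(60))
  root <- "GO:0008150"; sig_parent <- "GO:0023052"; bg_parent <- "GO:0008152"
  parents <- rbind(
    data.frame(child = c(sig_parent, bg_parent), parent = root),
    data.frame(child = sig_leaves, parent = sig_parent),
    data.frame(child = bg_leaves, parent = bg_parent))
  graph <- go_graph(c(root, sig_parent, bg_parent, sig_leaves, bg_leaves),
                    parents)
  annotations <- list()
  for (c in seq_len(spec$n_candidates)) {
    p <- paths[[c]]
    for (k in seq_along(p)) {
      # position k gets signaling leaf k (+ its parent, exercising the
      # leaf restriction); shared across petals so rules generalize
      annotations[[p[k]]] <- unique(c(annotations[[p[k]]],
                                      sig_leaves[k], sig_parent))
    }
  }
  for (gn in sample(bg_rows, round(0.8 * length(bg_rows)))) {
    annotations[[gn]] <- sample(bg_leaves, sample(1:2, 1L))
  }
  pathways <- stats::setNames(paths, sprintf("PATHWAY_%s", candidates))

  ## ---- families, localization, training labels ----
  fams <- sprintf("PF%05d", seq_len(spec$n_families))
  fam_genes <- sample(bg_rows, round(0.4 * length(bg_rows)))
  family_map <- stats::setNames(as.list(sample(fams, length(fam_genes),
                                               replace = TRUE)), fam_genes)
  # planted-path proteins get petal-specific families so the imputation
  # stage can restore a planted edge the reliability filter drops (family
  # evidence comes from the surviving sibling edges of the same petal)
  family_map[[driver]] <- "PF_DRIVER"
  for (c in seq_len(spec$n_candidates)) {
    for (gn in setdiff(paths[[c]], driver)) {
      family_map[[gn]] <- sprintf("PF_PETAL%d", c)
    }
  }
  comps <- c("nucleus", "cytoplasm", "membrane", "mitochondrion",
             "er", "golgi")
  localization <- stats::setNames(
    lapply(genes, function(g) sample(comps, sample(1:2, 1L))), genes)
  # trusted (positive) edges: a sample of the reliable set, like a curated
  # reference interaction database
  rel_keys <- paste(pmin(reliable$from, reliable$to),
                    pmax(reliable$from, reliable$to), sep = "|")
  trusted <- sample(rel_keys, min(200L, length(rel_keys)))

  truth <- list(driver = driver, candidates = candidates,
                planted_candidate = candidates[1L], paths = paths,
                targets = targets, true_targets = true_targets,
                target_signs = signs, unreliable = unreliable_keys,
                loadings = list(petal = lp, driver = spec$driver_loading,
                                coupling = phi, target = lt),
                shift = spec$shift, spec = unclass(spec))
  bundle <- list(network = network, expression = expression,
                 annotations = annotations, go_graph = graph,
                 pathways = pathways, family_map = family_map,
                 localization = localization, targets = targets,
                 trusted_edges = trusted, truth = truth)
  if (!is.null(dir)) write_fixture(bundle, dir)
  bundle
}

#' Write a fixture bundle to a directory in standard formats
#'
#' @param bundle result of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_edge_list(bundle$network, p("network.tsv"))
  write_expression(bundle$expression, p("expression.tsv"), p("groups.tsv"))
  write_gaf(bundle$annotations, p("annotations.gaf"))
  write_obo(bundle$go_graph, p("go.obo"))
  write_gmt(bundle$pathways, p("pathways.gmt"))
  write_pair_map(bundle$family_map, p("families.tsv"))
  write_pair_map(bundle$localization, p("localization.tsv"))
  write_target_list(bundle$targets, p("targets.txt"))
  writeLines(bundle$trusted_edges, p("trusted_edges.txt"))
  write_target_list(bundle$truth$candidates, p("candidates.txt"))
  jsonlite::write_json(bundle$truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Check the planted properties of a generated fixture
#'
#' Verifies that the planted structure actually holds in the generated
#' data: every planted path is realized in the network and lies within
#' the driver-candidate diameter bound; empirical correlations along the
#' planted path edges are within 3 standard errors (Fisher z scale) of
#' the value implied by the factor model (including the group-shift
#' contribution to pooled correlation); targets are on the array; the
#' planted unreliable edges are present.
#'
#' @param bundle result of [generate_fixture()].
#' @return data.frame with columns `property`, `pass`, `detail`.
#' @export
fixture_truth_check <- function(bundle) {
  truth <- bundle$truth
  spec <- truth$spec
  checks <- list()
  add <- function(property, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      property = property, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  ek <- edge_keys(bundle$network)
  for (cand in truth$candidates) {
    path <- truth$paths[[cand]]
    pk <- paste(pmin(path[-length(path)], path[-1L]),
                pmax(path[-length(path)], path[-1L]), sep = "|")
    add(paste0("path_realized_", cand), all(pk %in% ek))
    d <- shortest_path_distance(bundle$network, truth$driver, cand)
    add(paste0("path_within_bound_", cand),
        is.finite(d) && d <= length(path) - 1L, paste("d =", d))
  }
  # model-implied pooled correlation of adjacent petal genes:
  # signal lp^2 (or driver_loading*coupling*lp for the driver edge) plus
  # the shift term shift^2/4, normalized by the shifted variances
  n <- ncol(bundle$expression$values)
  se3 <- 3 / sqrt(n - 3)  # Fisher z standard error
  vshift <- 1 + spec$shift^2 / 4
  vals <- bundle$expression$values
  for (cand in truth$candidates) {
    path <- truth$paths[[cand]]
    for (i in seq_len(length(path) - 1L)) {
      sig <- if (path[i] == truth$driver) {
        truth$loadings$driver * truth$loadings$coupling * truth$loadings$petal
      } else {
        truth$loadings$petal^2
      }
      expect_r <- (sig + spec$shift^2 / 4) / vshift
      obs_r <- stats::cor(vals[path[i], ], vals[path[i + 1L], ])
      ok <- abs(atanh(min(obs_r, 0.9999)) - atanh(expect_r)) <= se3
      add(paste0("edge_r_", path[i], "_", path[i + 1L]), ok,
          sprintf("obs %.2f vs model %.2f", obs_r, expect_r))
    }
  }
  # true-target correlation with a planted petal gene (not the driver)
  petal1 <- setdiff(truth$paths[[truth$planted_candidate]], truth$driver)
  expect_rt <- truth$loadings$petal * truth$loadings$target / sqrt(vshift)
  for (j in seq_along(truth$true_targets)) {
    obs_r <- stats::cor(vals[truth$true_targets[j], ], vals[petal1[1L], ])
    ok <- abs(atanh(obs_r) - atanh(truth$target_signs[j] * expect_rt)) <= se3
    add(paste0("target_r_", truth$true_targets[j]), ok,
        sprintf("obs %.2f vs model %.2f", obs_r,
                truth$target_signs[j] * expect_rt))
  }
  add("targets_on_array",
      all(truth$targets %in% rownames(vals)))
  add("unreliable_edges_present", all(truth$unreliable %in% ek))
  do.call(rbind, checks)
}
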