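#' Build and validate a pipeline run configuration
#'
#' Collects input paths and tuning parameters for the refine -> blossom ->
#' rank pipeline. Defaults match the method's published operating point:
#' gamma = 0.6, p_threshold = 0.05, 10000 permutations, 100 training
#' repeats. All randomness flows from one master seed via named
#' substreams.
#'
#' @param input_dir directory holding the standard input files (as written
#'   by [write_fixture()]); individual paths may be overridden.
#' @param out_dir output directory.
#' @param driver driver gene ID.
#' @param candidates character vector of candidate genes, or NULL to read
#'   `candidates.txt` from `input_dir`.
#' @param gamma path coexpression threshold in (0, 1).
#' @param p_threshold rule-significance threshold in (0, 1).
#' @param n_perm permutations for petal ranking.
#' @param n_null null paths per path-significance test.
#' @param min_support minimum association-rule support.
#' @param n_repeats training repeats for the reliability model.
#' @param n_negative negative training edges sampled when no negative list
#'   is supplied.
#' @param cutoff optional reliability-cutoff override.
#' @param seed master seed.
#' @param paths named list overriding individual input paths (keys:
#'   edge_list, expression_matrix, expression_groups, gaf, obo, gmt,
#'   families, localization, targets, trusted_edges, candidates).
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir, driver, candidates = NULL,
                       gamma = 0.6, p_threshold = 0.05, n_perm = 10000L,
                       n_null = 1000L, min_support = 1L, n_repeats = 100L,
                       n_negative = 200L, cutoff = NULL, seed = 1L,
                       paths = list()) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma >= 1)
    stop("gamma must be in (0, 1)")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must be in (0, 1)")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  default <- function(key, file) {
    if (!is.null(paths[[key]])) paths[[key]] else file.path(input_dir, file)
  }
  cfg <- list(
    edge_list = default("edge_list", "network.tsv"),
    expression_matrix = default("expression_matrix", "expression.tsv"),
    expression_groups = default("expression_groups", "groups.tsv"),
    gaf = default("gaf", "annotations.gaf"),
    obo = default("obo", "go.obo"),
    gmt = default("gmt", "pathways.gmt"),
    families = default("families", "families.tsv"),
    localization = default("localization", "localization.tsv"),
    targets = default("targets", "targets.txt"),
    trusted_edges = default("trusted_edges", "trusted_edges.txt"),
    candidates_file = default("candidates", "candidates.txt"),
    out_dir = out_dir, driver = driver, candidates = candidates,
    gamma = gamma, p_threshold = p_threshold,
    n_perm = as.integer(n_perm), n_null = as.integer(n_null),
    min_support = as.integer(min_support),
    n_repeats = as.integer(n_repeats), n_negative = as.integer(n_negative),
    cutoff = cutoff, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

read_config_inputs <- function(config) {
  for (key in c("edge_list", "expression_matrix", "expression_groups",
                "gaf", "obo", "gmt", "families", "localization",
                "targets")) {
    if (!file.exists(config[[key]]))
      stop("input file not readable: ", config[[key]])
  }
  candidates <- config$candidates
  if (is.null(candidates)) candidates <- read_target_list(config$candidates_file)
  list(network = read_edge_list(config$edge_list),
       expression = read_expression(config$expression_matrix,
                                    config$expression_groups),
       annotations = read_gaf(config$gaf),
       go_graph = read_obo(config$obo),
       pathways = read_gmt(config$gmt),
       family_map = read_pair_map(config$families),
       localization = read_pair_map(config$localization),
       targets = read_target_list(config$targets),
       trusted = if (file.exists(config$trusted_edges))
         readLines(config$trusted_edges) else character(0),
       candidates = candidates)
}

#' Refinement stage: G -> G' -> G''
#'
#' Computes edge features, trains the reliability model on trusted
#' (positive) edges against randomly sampled other edges, filters the
#' network at the trained (or overridden) cutoff, and imputes family
#' edges.
#'
#' @param inputs list from the internal input reader (network, expression,
#'   localization, family_map, trusted).
#' @param config a `run_config`.
#' @return list with `G`, `G_prime`, `G_imputed`, `model`, `removed`, and
#'   stage counters.
#' @export
pipeline_refine <- function(inputs, config) {
  feats <- compute_edge_features(inputs$network, inputs$expression,
                                 inputs$localization)
  all_keys <- paste(feats$from, feats$to, sep = "|")
  positives <- intersect(inputs$trusted, all_keys)
  if (length(positives) < 2L)
    stop("need >= 2 trusted edges present in the network")
  pool <- setdiff(all_keys, positives)
  negatives <- withr::with_seed(derive_seed(config$seed, "negatives"), {
    sample(pool, min(config$n_negative, length(pool)))
  })
  model <- train_reliability_model(feats, positives, negatives,
                                   n_repeats = config$n_repeats,
                                   seed = derive_seed(config$seed, "train"))
  filt <- filter_network(inputs$network, model, feats, cutoff = config$cutoff)
  g2 <- impute_edges(filt$network, inputs$family_map)
  list(G = inputs$network, G_prime = filt$network, G_imputed = g2,
       model = model, removed = filt$removed,
       counters = list(edges_raw = igraph::ecount(inputs$network),
                       edges_removed = nrow(filt$removed),
                       edges_kept = igraph::ecount(filt$network),
                       edges_imputed = igraph::ecount(g2) -
                         igraph::ecount(filt$network)))
}

#' Blossom stage: mine petals from the refined network
#'
#' @param inputs input list.
#' @param refined result of [pipeline_refine()].
#' @param config a `run_config`.
#' @return list with the `blossom`, mined `rules`, `leaf_ann`,
#'   `coexpr_map`, and counters.
#' @export
pipeline_blossom <- function(inputs, refined, config) {
  missing <- setdiff(c(config$driver, inputs$candidates),
                     igraph::V(refined$G)$name)
  if (length(missing)) stop("driver/candidate gene(s) not in network: ",
                            paste(missing, collapse = ", "))
  leaf_ann <- leaf_annotations(inputs$annotations, inputs$go_graph)
  rules <- mine_rules(inputs$pathways, leaf_ann, refined$G_imputed,
                      min_support = config$min_support)
  coexpr_map <- pearson_map(inputs$expression)
  blossom <- build_blossom(config$driver, inputs$candidates, refined$G,
                           refined$G_imputed, coexpr_map, rules, leaf_ann,
                           gamma = config$gamma,
                           p_threshold = config$p_threshold,
                           n_null = config$n_null,
                           seed = derive_seed(config$seed, "blossom"))
  n_paths <- sum(vapply(blossom$petals, function(p) nrow(p$paths), 0L))
  n_kept <- sum(vapply(blossom$petals, function(p) sum(p$paths$kept), 0L))
  list(blossom = blossom, rules = rules, leaf_ann = leaf_ann,
       coexpr_map = coexpr_map,
       counters = list(rules_mined = nrow(rules),
                       paths_scored = n_paths, paths_kept = n_kept,
                       petals = length(blossom$petals)))
}

#' Ranking stage: test each petal's bimodality against the targets
#'
#' @param inputs input list.
#' @param bloomed result of [pipeline_blossom()].
#' @param config a `run_config`.
#' @return list with the ranking data.frame and activity table.
#' @export
pipeline_rank <- function(inputs, bloomed, config) {
  act <- activity(inputs$expression)
  ranking <- rank_petals(bloomed$blossom, inputs$targets, act,
                         bloomed$coexpr_map, n_perm = config$n_perm,
                         seed = derive_seed(config$seed, "rank"))
  list(ranking = ranking, activity = act)
}

#' Run the full pipeline: refine -> blossom -> rank
#'
#' Executes the three stages, writes one petal file per candidate
#' (GraphML), the ranking report (TSV + JSON), the trained model, and a
#' run manifest (configuration echo, seed, package version, input
#' checksums, stage counters). Output is a pure function of (inputs,
#' config, seed): re-running reproduces byte-identical ranking files.
#'
#' @param config a `run_config`.
#' @return list with `refined`, `bloomed`, `ranked`, `manifest`
#'   (invisibly); side effect: files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- read_config_inputs(config)
  refined <- pipeline_refine(inputs, config)
  bloomed <- pipeline_blossom(inputs, refined, config)
  ranked <- pipeline_rank(inputs, bloomed, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  for (cand in names(bloomed$blossom$petals)) {
    write_petal(bloomed$blossom$petals[[cand]],
                out(sprintf("petal_%s.graphml", cand)), "graphml")
  }
  ranking <- ranked$ranking
  utils::write.table(ranking, out("ranking.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(ranking, out("ranking.json"), dataframe = "rows",
                       digits = NA)
  jsonlite::write_json(list(coefficients = as.list(refined$model$coefficients),
                            cutoff = refined$model$cutoff,
                            n_repeats = refined$model$n_repeats,
                            seed = refined$model$seed),
                       out("reliability_model.json"), auto_unbox = TRUE,
                       digits = NA)
  input_files <- unlist(config[c("edge_list", "expression_matrix",
                                 "expression_groups", "gaf", "obo", "gmt",
                                 "families", "localization", "targets")])
  manifest <- list(
    config = config[setdiff(names(config), "candidates")],
    candidates = inputs$candidates,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("petals")),
    input_md5 = as.list(tools::md5sum(input_files)),
    counters = c(refined$counters, bloomed$counters))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(refined = refined, bloomed = bloomed, ranked = ranked,
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic input bundle), `refine`,
#' `blossom`, `rank` (run the pipeline up to the named stage), and `run`
#' (all stages). Exit codes: 0 ok, 1 input/usage error, 2 runtime failure.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit code, invisibly.
#' @export
petals_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: petals <simulate|refine|blossom|rank|run> [options]",
    "  simulate --out DIR [--seed N]",
    "  run      --input DIR --out DIR --driver GENE [--candidates FILE]",
    "           [--gamma X] [--p-threshold X] [--n-perm N] [--seed N]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]
  opts <- parse_cli_opts(args[-1L])
  get <- function(key, default = NULL) {
    if (!is.null(opts[[key]])) opts[[key]] else default
  }
  status <- tryCatch({
    if (cmd == "simulate") {
      out <- get("out"); if (is.null(out)) stop("simulate needs --out")
      spec <- fixture_spec(seed = as.integer(get("seed", 1L)))
      generate_fixture(spec, dir = out)
      message("fixture written to ", out)
      0L
    } else if (cmd %in% c("refine", "blossom", "rank", "run")) {
      input <- get("input"); out <- get("out"); driver <- get("driver")
      if (is.null(input) || is.null(out) || is.null(driver))
        stop(cmd, " needs --input, --out, --driver")
      cfg <- run_config(
        input_dir = input, out_dir = out, driver = driver,
        candidates = if (!is.null(get("candidates")))
          read_target_list(get("candidates")) else NULL,
        gamma = as.numeric(get("gamma", 0.6)),
        p_threshold = as.numeric(get("p-threshold", 0.05)),
        n_perm = as.integer(get("n-perm", 10000L)),
        n_null = as.integer(get("n-null", 1000L)),
        seed = as.integer(get("seed", 1L)))
      inputs <- read_config_inputs(cfg)
      refined <- pipeline_refine(inputs, cfg)
      if (cmd == "refine") {
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_edge_list(refined$G_imputed, file.path(out, "refined.tsv"),
                        provenance = TRUE)
      } else if (cmd == "blossom") {
        bloomed <- pipeline_blossom(inputs, refined, cfg)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        for (cand in names(bloomed$blossom$petals)) {
          write_petal(bloomed$blossom$petals[[cand]],
                      file.path(out, sprintf("petal_%s.graphml", cand)),
                      "graphml")
        }
      } else {
        run_pipeline(cfg)
      }
      0L
    } else {
      message("unknown command: ", cmd, "\n", usage)
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("needs --|not readable|unknown|must be", conditionMessage(e)))
      1L else 2L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[[i + 1L]]; i <- i + 2L
    }
  }
  opts
}
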