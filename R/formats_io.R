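#' Read a tab- or whitespace-separated interaction edge list
#'
#' Expects two or three columns per line: geneA, geneB, and an optional
#' observation count (default 1). Repeated lines for the same unordered
#' pair sum their counts; self-loop lines are skipped with a warning.
#'
#' @param path file path.
#' @param dialect field separator regime: `"tsv"` (tab) or `"whitespace"`.
#' @return an `igraph` interaction network (see [interaction_network()]).
#' @export
read_edge_list <- function(path, dialect = c("whitespace", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(interaction_network())
  split_re <- if (dialect == "tsv") "\t" else "[ \t]+"
  parts <- strsplit(trimws(lines), split_re)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop("malformed edge-list line ", bad[1L], ": expected 2-3 fields, got ",
         nf[bad[1L]])
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  cnt <- vapply(parts, function(p) {
    if (length(p) >= 3L) suppressWarnings(as.integer(p[[3L]])) else 1L
  }, 1L)
  if (anyNA(cnt)) {
    stop("malformed edge-list line ", which(is.na(cnt))[1L],
         ": non-integer observation count")
  }
  interaction_network(data.frame(from = from, to = to,
                                 observation_count = cnt,
                                 stringsAsFactors = FALSE))
}

#' Write an interaction network as a tab-separated edge list
#'
#' @param network `igraph` interaction network.
#' @param path output file.
#' @param provenance if TRUE a fourth column with the provenance flag is
#'   written (non-standard; used by the fixture round-trip).
#' @export
write_edge_list <- function(network, path, provenance = FALSE) {
  df <- network_edges(network)
  cols <- if (provenance) df else df[, c("from", "to", "observation_count")]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an expression bundle
#'
#' Container for a genes-by-samples matrix of normalized expression
#' intensities plus a wild-type / mutant group label per sample.
#'
#' @param values numeric matrix, rows = genes (rownames required),
#'   columns = samples (colnames required).
#' @param group character/factor of per-sample labels in `{"WT","MT"}`,
#'   aligned with `colnames(values)` (may be named; then it is reordered).
#' @return object of class `expression_bundle`.
#' @export
expression_bundle <- function(values, group) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate gene row: ", dup)
  }
  nm <- names(group)
  group <- stats::setNames(as.character(group), nm)
  if (!is.null(names(group))) {
    missing <- setdiff(colnames(values), names(group))
    if (length(missing)) stop("sample(s) missing from groups: ",
                              paste(missing, collapse = ", "))
    group <- group[colnames(values)]
  }
  if (length(group) != ncol(values)) stop("group length != number of samples")
  if (!all(group %in% c("WT", "MT"))) stop("group labels must be WT or MT")
  structure(list(values = values, group = unname(group)),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat("expression_bundle:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", sum(x$group == "WT"), "WT /", sum(x$group == "MT"), "MT )\n")
  invisible(x)
}

#' Read an expression matrix with a sample-group sidecar
#'
#' @param matrix_path TSV with header row of sample IDs; first column holds
#'   gene IDs.
#' @param groups_path two-column TSV (sample ID, WT|MT), no header.
#' @return an `expression_bundle`.
#' @export
read_expression <- function(matrix_path, groups_path) {
  tab <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene row: ", genes[duplicated(genes)][1L])
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- genes
  grp <- utils::read.table(groups_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  group <- stats::setNames(as.character(grp[[2L]]), as.character(grp[[1L]]))
  expression_bundle(values, group)
}

#' Write an expression bundle to matrix + groups TSV files
#'
#' @param bundle an `expression_bundle`.
#' @param matrix_path,groups_path output paths.
#' @export
write_expression <- function(bundle, matrix_path, groups_path) {
  df <- data.frame(gene = rownames(bundle$values), bundle$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(colnames(bundle$values), bundle$group),
                     groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(matrix_path)
}

#' Read GO annotations from a GAF 2.x file
#'
#' Keeps only (DB Object Symbol, GO ID) pairs from the biological-process
#' aspect (column 9 == "P"). Lines starting with "!" are headers.
#'
#' @param path GAF file.
#' @return named list: gene -> character vector of GO term IDs.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p) length(p) >= 9L && p[[9L]] == "P", TRUE)
  parts <- parts[keep]
  gene <- vapply(parts, `[[`, "", 3L)
  term <- vapply(parts, `[[`, "", 5L)
  ann <- split(term, gene)
  lapply(ann, function(x) sort(unique(x)))
}

#' Write a minimal GAF 2.2 file from an annotation map
#'
#' @param annotations named list gene -> GO term IDs (biological process).
#' @param path output file.
#' @param db database label for column 1.
#' @export
write_gaf <- function(annotations, path, db = "SYNTH") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (gene in names(annotations)) {
    for (term in annotations[[gene]]) {
      writeLines(paste(db, gene, gene, "", term, "SYNTH:0", "IEA", "", "P",
                       "", "", "protein", "taxon:10090", "20100101", db,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a GO graph from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, keeping `is_a` and `relationship: part_of`
#' links. Obsolete terms are dropped.
#'
#' @param path OBO file.
#' @param namespace if non-NULL, keep only terms of this namespace (e.g.
#'   `"biological_process"`); terms without a namespace line are kept.
#' @return object of class `go_graph`: list with `terms` (character) and
#'   `parents` (data.frame child, parent).
#' @export
read_obo <- function(path, namespace = "biological_process") {
  lines <- readLines(path)
  terms <- character(); child <- character(); parent <- character()
  cur <- NULL; cur_ns <- NA_character_; cur_parents <- character()
  cur_obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !cur_obsolete &&
        (is.null(namespace) || is.na(cur_ns) || cur_ns == namespace)) {
      terms <<- c(terms, cur)
      if (length(cur_parents)) {
        child <<- c(child, rep(cur, length(cur_parents)))
        parent <<- c(parent, cur_parents)
      }
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; cur_ns <- NA_character_; cur_parents <- character()
      cur_obsolete <- FALSE; in_term <- TRUE
    } else if (startsWith(ln, "[")) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) {
        cur <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "namespace:")) {
        cur_ns <- trimws(sub("^namespace:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        cur_parents <- c(cur_parents,
                         trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
      } else if (startsWith(ln, "relationship: part_of")) {
        cur_parents <- c(cur_parents,
                         trimws(sub("!.*$", "", sub("^relationship: part_of", "", ln))))
      } else if (startsWith(ln, "is_obsolete: true")) {
        cur_obsolete <- TRUE
      }
    }
  }
  flush()
  keep <- parent %in% terms
  go_graph(terms, data.frame(child = child[keep], parent = parent[keep],
                             stringsAsFactors = FALSE))
}

#' Construct a GO graph object
#'
#' @param terms character vector of term IDs.
#' @param parents data.frame with columns `child`, `parent` (is_a/part_of
#'   links pointing from the more specific to the more general term).
#' @return object of class `go_graph`.
#' @export
go_graph <- function(terms, parents) {
  stopifnot(all(c("child", "parent") %in% names(parents)))
  terms <- unique(c(as.character(terms), parents$child, parents$parent))
  g <- igraph::graph_from_data_frame(parents[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_acyclic(g)) stop("GO graph contains a cycle")
  structure(list(terms = terms,
                 parents = data.frame(child = as.character(parents$child),
                                      parent = as.character(parents$parent),
                                      stringsAsFactors = FALSE)),
            class = "go_graph")
}

#' Write a GO graph as a minimal OBO 1.2 file
#'
#' @param graph `go_graph` object.
#' @param path output file.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(graph$parents$parent, graph$parents$child)
  for (t in graph$terms) {
    writeLines(c("[Term]", paste0("id: ", t), paste0("name: ", t),
                 "namespace: biological_process"), con)
    for (p in by_child[[t]]) writeLines(paste0("is_a: ", p), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors; every set has >= 2 members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    p <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(p) < 4L) stop("GMT line ", i, ": needs name, description, >=2 genes")
    out[[p[[1L]]]] <- unique(p[-(1:2)])
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param pathways named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, "synthetic", pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column gene-to-token map (family or localization TSV)
#'
#' One (gene, token) pair per line, tab separated. Used for Pfam-style
#' protein-family maps and subcellular-localization annotations.
#'
#' @param path TSV file.
#' @return named list: gene -> character vector of tokens.
#' @export
read_pair_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed map line ", bad[1L], ": expected 2 fields")
  gene <- vapply(parts, `[[`, "", 1L)
  tok <- vapply(parts, `[[`, "", 2L)
  lapply(split(tok, gene), function(x) sort(unique(x)))
}

#' @rdname read_pair_map
#' @param map named list gene -> tokens.
#' @export
write_pair_map <- function(map, path) {
  gene <- rep(names(map), lengths(map))
  tok <- unlist(map, use.names = FALSE)
  utils::write.table(data.frame(gene, tok), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one gene per line)
#'
#' @param path file path.
#' @return deduplicated character vector in file order.
#' @export
read_target_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (!length(x)) stop("empty target list: ", path)
  unique(x)
}

#' @rdname read_target_list
#' @param targets character vector of gene IDs.
#' @export
write_target_list <- function(targets, path) {
  writeLines(targets, path)
  invisible(path)
}

#' Write a petal subnetwork to disk
#'
#' @param petal a `petal` object (or bare `igraph` network).
#' @param path output file.
#' @param format one of `"graphml"`, `"sif"`, `"json"`. All three preserve
#'   nodes, edges and edge provenance on round trip.
#' @export
write_petal <- function(petal, path, format = c("graphml", "sif", "json")) {
  format <- match.arg(format)
  g <- if (inherits(petal, "petal")) petal$graph else petal
  df <- network_edges(g)
  nodes <- sort(igraph::V(g)$name)
  switch(format,
    graphml = igraph::write_graph(g, path, format = "graphml"),
    sif = {
      lines <- paste(df$from,
                     ifelse(df$provenance == "imputed", "imputed", "pp"),
                     df$to, sep = "\t")
      writeLines(c(lines, setdiff(nodes, c(df$from, df$to))), path)
    },
    json = jsonlite::write_json(list(nodes = nodes, edges = df), path,
                                dataframe = "rows", auto_unbox = FALSE)
  )
  invisible(path)
}

#' Read a petal subnetwork written by [write_petal()]
#'
#' @param path input file.
#' @param format one of `"graphml"`, `"sif"`, `"json"`.
#' @return an `igraph` interaction network.
#' @export
read_petal <- function(path, format = c("graphml", "sif", "json")) {
  format <- match.arg(format)
  switch(format,
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      interaction_network(network_edges(g), nodes = igraph::V(g)$name)
    },
    sif = {
      lines <- readLines(path)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      is_edge <- lengths(parts) >= 3L
      ep <- parts[is_edge]
      df <- data.frame(
        from = vapply(ep, `[[`, "", 1L),
        to = vapply(ep, `[[`, "", 3L),
        provenance = ifelse(vapply(ep, `[[`, "", 2L) == "imputed",
                            "imputed", "observed"),
        stringsAsFactors = FALSE)
      iso <- vapply(parts[!is_edge], `[[`, "", 1L)
      interaction_network(df, nodes = iso)
    },
    json = {
      x <- jsonlite::read_json(path, simplifyVector = TRUE)
      edges <- as.data.frame(x$edges, stringsAsFactors = FALSE)
      interaction_network(edges, nodes = unlist(x$nodes))
    }
  )
}
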