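#' Read a genes-by-samples expression matrix
#'
#' Expects a delimited text file whose first row holds sample identifiers and
#' whose first column holds gene symbols; every other cell must be a finite
#' number. Duplicate gene symbols are collapsed by keeping the row with the
#' highest variance (the usual probe-collapse heuristic); duplicate sample
#' identifiers are an error.
#'
#' @param path Path to the text file.
#' @param delimiter Field separator, tab by default.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to the values after
#'   reading. Values are otherwise taken as-is.
#' @return A numeric matrix, genes in rows (named), samples in columns (named).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("\tS1\tS2", "G1\t1\t2", "G2\t3\t4"), f)
#' read_expression_matrix(f)
#' @export
read_expression_matrix <- function(path, delimiter = "\t", log2_transform = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort(sprintf("'%s': need a header row and at least one gene row", path))
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a leading stub over the gene-symbol column
  n_body <- length(fields[[2]])
  samples <- if (length(header) == n_body) header[-1] else header
  if (length(samples) != n_body - 1) {
    abort(sprintf("'%s': header has %d sample ids but rows have %d value columns",
                  path, length(samples), n_body - 1))
  }
  if (anyDuplicated(samples)) {
    abort(sprintf("'%s': duplicate sample id '%s'", path,
                  samples[duplicated(samples)][1]))
  }
  body <- fields[-1]
  genes <- vapply(body, `[[`, character(1), 1)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_body) {
      abort(sprintf("'%s' line %d (gene %s): expected %d fields, found %d",
                    path, i + 1, row[1], n_body, length(row)))
    }
    v <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort(sprintf("'%s' line %d: non-numeric value '%s' for gene %s, sample %s",
                    path, i + 1, row[-1][bad[1]], row[1], samples[bad[1]]))
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(genes)) {
    rv <- apply(vals, 1, stats::var)
    keep <- unlist(lapply(split(seq_along(genes), genes), function(idx) {
      idx[which.max(rv[idx])]
    }), use.names = FALSE)
    keep <- sort(keep)
    dropped <- length(genes) - length(keep)
    inform(sprintf("collapsed %d duplicate gene row(s) by maximum variance", dropped))
    vals <- vals[keep, , drop = FALSE]
  }
  if (log2_transform) vals <- log2(vals + 1)
  vals
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored; surrounding
#' whitespace is stripped; duplicates are dropped. Case is preserved (symbols
#' are opaque, case-sensitive strings; no alias resolution is attempted).
#'
#' @param path Path to the list file.
#' @return Character vector of unique symbols (possibly empty, with a warning).
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  out <- unique(lines[nzchar(lines)])
  if (length(out) == 0) warn(sprintf("'%s': no gene symbols found", path))
  out
}

#' Read gene sets in GMT format
#'
#' Each line is `term<TAB>description<TAB>gene1<TAB>gene2...`. Terms must be
#' unique and carry at least one gene.
#'
#' @param path Path to the GMT file.
#' @return Named list; each element is `list(description =, genes =)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(f) < 3 || !nzchar(f[1]) || length(genes) == 0) {
      abort(sprintf("'%s' line %d: GMT lines need term, description and >= 1 gene", path, i))
    }
    if (f[1] %in% names(out)) {
      abort(sprintf("'%s' line %d: duplicate term id '%s'", path, i, f[1]))
    }
    out[[f[1]]] <- list(description = f[2], genes = genes)
  }
  out
}

#' Read and write 4-column motif tables
#'
#' The interchange format for triplet sets is a tab-separated table with
#' columns `tf`, `modulator`, `target`, `score`. A header line is detected
#' automatically (first row whose fourth field is not numeric). Scores are
#' serialized with six significant digits so that repeated write/read cycles
#' and cross-run intersections are stable.
#'
#' @param path File path.
#' @param cohort,params Optional attributes attached to the returned set.
#' @return `read_motif_table()` returns a [triplet_set()];
#'   `write_motif_table()` returns `path` invisibly.
#' @export
read_motif_table <- function(path, cohort = NULL, params = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(triplet_set(cohort = cohort, params = params))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(fields)
  if (any(lens != 4)) {
    bad <- which(lens != 4)[1]
    abort(sprintf("'%s' line %d: expected 4 tab-separated columns, found %d",
                  path, bad, lens[bad]))
  }
  first_score <- suppressWarnings(as.numeric(fields[[1]][4]))
  if (is.na(first_score)) fields <- fields[-1]  # header row
  if (length(fields) == 0) return(triplet_set(cohort = cohort, params = params))
  m <- do.call(rbind, fields)
  score <- suppressWarnings(as.numeric(m[, 4]))
  if (any(is.na(score))) {
    bad <- which(is.na(score))[1] + if (is.na(first_score)) 1 else 0
    abort(sprintf("'%s' line %d: score '%s' is not numeric", path, bad,
                  m[which(is.na(score))[1], 4]))
  }
  triplet_set(
    modulator = m[, 2], tf = m[, 1], target = m[, 3], score = score,
    sign = ifelse(score >= 0, "positive", "negative"),
    cohort = cohort, params = params
  )
}

#' @param motifs A [triplet_set()].
#' @param header Write a header line? Default `TRUE`.
#' @rdname read_motif_table
#' @export
write_motif_table <- function(motifs, path, header = TRUE) {
  stopifnot(inherits(motifs, "triplet_set"))
  rows <- sprintf("%s\t%s\t%s\t%s", motifs$tf, motifs$modulator, motifs$target,
                  formatC(motifs$score, digits = 6, format = "g"))
  if (header) rows <- c("tf\tmodulator\ttarget\tscore", rows)
  writeLines(rows, path)
  invisible(path)
}

#' Export a hierarchical network to standard file formats
#'
#' Writes Cytoscape-compatible representations of a [build_network()] result:
#' SIF (`modulates` / `regulates` interaction labels), GraphML, and/or plain
#' TSV node and edge attribute tables. Re-importing the edge table with
#' [read_edge_table()] reconstructs the same typed edge set.
#'
#' @param network A `hierarchical_network`.
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("sif", "graphml", "tables")`.
#' @param basename Stem for the output file names.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, dir, formats = c("sif", "graphml", "tables"),
                           basename = "network") {
  stopifnot(inherits(network, "hierarchical_network"))
  if (nrow(network$edges) == 0) abort("refusing to export an empty network")
  known <- c("sif", "graphml", "tables")
  bad <- setdiff(formats, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown export format '%s'; supported: %s",
                  bad[1], paste(known, collapse = ", ")))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  interaction <- ifelse(network$edges$type == "modulation", "modulates", "regulates")
  if ("sif" %in% formats) {
    p <- file.path(dir, paste0(basename, ".sif"))
    writeLines(sprintf("%s\t%s\t%s", network$edges$from, interaction,
                       network$edges$to), p)
    paths <- c(paths, p)
  }
  if ("graphml" %in% formats) {
    p <- file.path(dir, paste0(basename, ".graphml"))
    igraph::write_graph(network$graph, p, format = "graphml")
    paths <- c(paths, p)
  }
  if ("tables" %in% formats) {
    pn <- file.path(dir, paste0(basename, "_nodes.tsv"))
    pe <- file.path(dir, paste0(basename, "_edges.tsv"))
    readr::write_tsv(network$nodes, pn)
    readr::write_tsv(network$edges[, c("from", "to", "type", "n_motifs")], pe)
    paths <- c(paths, pn, pe)
  }
  invisible(paths)
}

#' @param path Path to an edge table written by [export_network()].
#' @rdname export_network
#' @return `read_edge_table()` returns a tibble with columns `from`, `to`,
#'   `type` (and `n_motifs` if present).
#' @export
read_edge_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML file describing a [run_pipeline()] run and validates the
#' basics: a non-negative integer seed and resolvable input paths.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  seed <- cfg$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1 || seed < 0 || seed != floor(seed)) {
    abort("config: 'seed' must be a single non-negative integer")
  }
  cfg$seed <- as.integer(seed)
  for (key in intersect(names(cfg), c("expression", "disease_genes", "tf_list",
                                      "oncogene_list", "tsg_list", "gmt"))) {
    paths <- unlist(cfg[[key]], use.names = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      abort(sprintf("config: path for '%s' does not exist: %s", key, missing[1]))
    }
  }
  cfg
}
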