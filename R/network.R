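#' Build the three-layer hierarchical regulatory network
#'
#' Collapses a motif set into a typed directed graph: one `modulation` edge
#' per distinct (modulator, TF) pair and one `regulation` edge per distinct
#' (TF, target) pair, each annotated with the number of supporting motifs.
#' Nodes carry role flags (`oncogene_modulator`, `tsg_modulator`, `tf`,
#' `target`); a gene occupying several layers receives every applicable flag.
#'
#' @param motifs A [triplet_set()].
#' @param catalog A [build_catalog()] object used to classify modulators into
#'   oncogenes and TSGs; every motif TF must be in `catalog$tfs` and every
#'   motif modulator in `catalog$modulators`.
#' @return An object of class `hierarchical_network`: list with `graph` (an
#'   igraph), `nodes` (tibble of flags), `edges` (tibble `from`, `to`,
#'   `type`, `n_motifs`), and `summary` (layer sizes).
#' @export
build_network <- function(motifs, catalog) {
  stopifnot(inherits(motifs, "triplet_set"), inherits(catalog, "gene_catalog"))
  if (nrow(motifs) == 0) abort("cannot build a network from an empty motif set")
  bad_tf <- setdiff(unique(motifs$tf), catalog$tfs)
  if (length(bad_tf) > 0) {
    abort(sprintf("motif TF '%s' is not a catalog TF", bad_tf[1]))
  }
  bad_m <- setdiff(unique(motifs$modulator), catalog$modulators)
  if (length(bad_m) > 0) {
    abort(sprintf("motif modulator '%s' is not a catalog modulator", bad_m[1]))
  }
  mod_edges <- motifs |>
    as_tibble() |>
    dplyr::count(from = .data$modulator, to = .data$tf, name = "n_motifs") |>
    dplyr::mutate(type = "modulation")
  reg_edges <- motifs |>
    as_tibble() |>
    dplyr::count(from = .data$tf, to = .data$target, name = "n_motifs") |>
    dplyr::mutate(type = "regulation")
  edges <- dplyr::bind_rows(mod_edges, reg_edges)[, c("from", "to", "type", "n_motifs")]

  genes <- sort(unique(c(motifs$modulator, motifs$tf, motifs$target)))
  mods <- unique(motifs$modulator)
  nodes <- tibble(
    gene = genes,
    oncogene_modulator = genes %in% intersect(mods, catalog$oncogenes),
    tsg_modulator = genes %in% intersect(mods, catalog$tsgs),
    tf = genes %in% unique(motifs$tf),
    target = genes %in% unique(motifs$target)
  )
  graph <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                         vertices = as.data.frame(nodes))
  summary <- tibble(
    layer = c("modulators", "oncogene_modulators", "tsg_modulators", "tfs",
              "targets"),
    n = c(length(mods), sum(nodes$oncogene_modulator), sum(nodes$tsg_modulator),
          sum(nodes$tf), sum(nodes$target))
  )
  structure(list(graph = graph, nodes = nodes, edges = edges, summary = summary),
            class = "hierarchical_network")
}

#' @export
print.hierarchical_network <- function(x, ...) {
  cat(sprintf("<hierarchical_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(x$summary)
  invisible(x)
}

#' Layer and edge counts of a hierarchical network
#'
#' @param x A `hierarchical_network`.
#' @param ... Unused.
#' @return One-row tibble of node, edge and layer counts.
#' @method glance hierarchical_network
#' @export
glance.hierarchical_network <- function(x, ...) {
  s <- setNames(x$summary$n, x$summary$layer)
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_modulation_edges = sum(x$edges$type == "modulation"),
    n_regulation_edges = sum(x$edges$type == "regulation"),
    n_modulators = unname(s["modulators"]),
    n_oncogene_modulators = unname(s["oncogene_modulators"]),
    n_tsg_modulators = unname(s["tsg_modulators"]),
    n_tfs = unname(s["tfs"]), n_targets = unname(s["targets"])
  )
}

#' Enumerate regulatory loops
#'
#' Finds simple directed cycles of length at most `max_len` in the union of
#' modulation and regulation edges. Loops arise when a gene occupies several
#' layers (for example a TF whose target modulates it back); each loop is
#' reported once, as an ordered node cycle starting at its lexicographically
#' smallest node.
#'
#' @param network A `hierarchical_network`.
#' @param max_len Maximum cycle length; 2 (reciprocal pairs) by default.
#' @return List of character vectors, one per loop.
#' @export
find_regulatory_loops <- function(network, max_len = 2) {
  stopifnot(inherits(network, "hierarchical_network"))
  edges <- unique(network$edges[, c("from", "to")])
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  loops <- list()
  # DFS restricted to nodes >= start (lexicographic) so each cycle is found
  # exactly once, anchored at its smallest node
  walk <- function(start, path) {
    last <- path[length(path)]
    for (nxt in adj[[last]]) {
      if (nxt == start && length(path) >= 2) {
        loops[[length(loops) + 1L]] <<- path
      } else if (length(path) < max_len && nxt > start && !(nxt %in% path)) {
        walk(start, c(path, nxt))
      }
    }
  }
  for (s in nodes) walk(s, s)
  loops
}

#' Target-layer genes that also occupy an upper layer
#'
#' @param network A `hierarchical_network`.
#' @return Character vector of target genes that are also flagged as TF or
#'   modulator.
#' @export
multi_role_targets <- function(network) {
  stopifnot(inherits(network, "hierarchical_network"))
  n <- network$nodes
  n$gene[n$target & (n$tf | n$oncogene_modulator | n$tsg_modulator)]
}

#' Node centralities of the hierarchical network
#'
#' Degrees are counted on the typed edge multiset; betweenness is directed
#' shortest-path betweenness normalized by `(n-1)(n-2)`; closeness is
#' directed harmonic closeness, `mean(1 / d(u, v))` over all other nodes with
#' unreachable pairs contributing zero — the natural convention for a layered
#' graph in which most ordered pairs are mutually unreachable.
#'
#' @param network A `hierarchical_network`.
#' @return Tibble: `gene`, `in_degree`, `out_degree`, `degree`,
#'   `betweenness`, `closeness`.
#' @export
centralities <- function(network) {
  stopifnot(inherits(network, "hierarchical_network"))
  g <- network$graph
  tibble(
    gene = igraph::V(g)$name,
    in_degree = as.integer(igraph::degree(g, mode = "in")),
    out_degree = as.integer(igraph::degree(g, mode = "out")),
    degree = as.integer(igraph::degree(g, mode = "all")),
    betweenness = unname(igraph::betweenness(g, directed = TRUE,
                                             normalized = TRUE)),
    closeness = unname(igraph::harmonic_centrality(g, mode = "out",
                                                   normalized = TRUE))
  )
}

#' Empirical topology significance of a node set
#'
#' Compares the observed mean centrality of a role set against `N` uniform
#' random node subsets of the same size (or against degree-preserving edge
#' rewirings of the whole graph, if `null = "rewire"`). The p-value uses the
#' add-one correction `p = (1 + #{null >= observed}) / (N + 1)` and so can
#' never be zero.
#'
#' @param network A `hierarchical_network`.
#' @param role_set Character vector of node names (non-empty, all present in
#'   the network).
#' @param metric One of `"degree"`, `"in_degree"`, `"out_degree"`,
#'   `"betweenness"`, `"closeness"`.
#' @param N Number of null draws (>= 100).
#' @param seed Integer seed; the draw sequence is fully reproducible.
#' @param null `"node_sets"` (random node subsets; the default) or
#'   `"rewire"` (degree-preserving rewiring null).
#' @return List with `observed`, `p_value`, `N`, `seed`, `metric`, `null`.
#' @export
topology_significance <- function(network, role_set,
                                  metric = c("degree", "in_degree",
                                             "out_degree", "betweenness",
                                             "closeness"),
                                  N = 1000, seed = 1,
                                  null = c("node_sets", "rewire")) {
  metric <- match.arg(metric)
  null <- match.arg(null)
  stopifnot(inherits(network, "hierarchical_network"))
  if (length(role_set) == 0) abort("role_set must be non-empty")
  if (N < 100) abort("N must be at least 100")
  cent <- centralities(network)
  missing <- setdiff(role_set, cent$gene)
  if (length(missing) > 0) {
    abort(sprintf("role_set gene(s) not in network: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  vals <- setNames(cent[[metric]], cent$gene)
  observed <- mean(vals[role_set])
  withr::local_seed(seed)
  if (null == "node_sets") {
    draws <- vapply(seq_len(N), function(i) {
      mean(vals[sample.int(length(vals), length(role_set))])
    }, numeric(1))
  } else {
    n_rewire <- max(10 * nrow(network$edges), 100)
    draws <- vapply(seq_len(N), function(i) {
      g2 <- igraph::rewire(network$graph,
                           igraph::keeping_degseq(niter = n_rewire))
      v2 <- switch(metric,
        degree = igraph::degree(g2, mode = "all"),
        in_degree = igraph::degree(g2, mode = "in"),
        out_degree = igraph::degree(g2, mode = "out"),
        betweenness = igraph::betweenness(g2, directed = TRUE, normalized = TRUE),
        closeness = igraph::harmonic_centrality(g2, mode = "out", normalized = TRUE)
      )
      mean(v2[role_set])
    }, numeric(1))
  }
  list(observed = observed, p_value = (1 + sum(draws >= observed)) / (N + 1),
       N = as.integer(N), seed = as.integer(seed), metric = metric, null = null)
}

#' TF in-degree versus out-degree correlation
#'
#' For each TF node, the in-degree is the number of modulators connecting
#' into it (modulation edges received) and the out-degree the number of
#' targets it regulates (regulation edges emitted); the association between
#' the two across TFs is summarised by Spearman rank correlation.
#'
#' @param network A `hierarchical_network`.
#' @return List with `estimate`, `p_value`, `n_tfs` and the per-TF degree
#'   tibble.
#' @export
degree_correlation <- function(network) {
  stopifnot(inherits(network, "hierarchical_network"))
  tfs <- network$nodes$gene[network$nodes$tf]
  if (length(tfs) < 3) abort("need at least 3 TF nodes")
  mod_e <- network$edges[network$edges$type == "modulation", ]
  reg_e <- network$edges[network$edges$type == "regulation", ]
  deg <- tibble(
    tf = tfs,
    in_degree = vapply(tfs, function(f) sum(mod_e$to == f), numeric(1)),
    out_degree = vapply(tfs, function(f) sum(reg_e$from == f), numeric(1))
  )
  if (length(unique(deg$in_degree)) == 1 || length(unique(deg$out_degree)) == 1) {
    abort("degenerate degree vectors: correlation undefined for constant degrees")
  }
  ct <- suppressWarnings(cor.test(deg$in_degree, deg$out_degree,
                                  method = "spearman", exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n_tfs = length(tfs), degrees = deg)
}
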