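#' Derive a function-specific subnetwork by backward mapping
#'
#' Implements the three-step bottom-up restriction: (1) the gene set is
#' mapped onto the bottom (target) layer; (2) TFs with a regulation edge into
#' a retained target are kept; (3) modulators with a modulation edge into a
#' retained TF are kept. Gene-set members that occur only in upper layers are
#' not used as seeds. Edges are restricted to the retained endpoints, so
#' every retained TF keeps at least one regulation edge and every retained
#' modulator at least one modulation edge.
#'
#' @param network A [build_network()] result.
#' @param gene_set Character vector of gene symbols (for example one term of
#'   [read_gmt()]).
#' @param name Label for the subnetwork.
#' @return An object of class `subnetwork`: list with `name`, `nodes`,
#'   `edges`, `role_counts` (per-flag tallies; a multi-role node counts once
#'   per flag), and `parent_signature` identifying the parent network.
#' @export
derive_subnetwork <- function(network, gene_set, name = "subnetwork") {
  stopifnot(inherits(network, "hierarchical_network") ||
              inherits(network, "subnetwork"))
  signature <- if (inherits(network, "subnetwork")) {
    network$parent_signature
  } else {
    paste(nrow(network$nodes), nrow(network$edges))
  }
  nodes <- network$nodes
  targets <- intersect(nodes$gene[nodes$target], gene_set)
  if (length(targets) == 0) {
    warn(sprintf("gene set '%s' does not touch the target layer: empty subnetwork",
                 name))
  }
  reg <- network$edges[network$edges$type == "regulation" &
                         network$edges$to %in% targets, ]
  tfs <- unique(reg$from)
  mod <- network$edges[network$edges$type == "modulation" &
                         network$edges$to %in% tfs, ]
  modulators <- unique(mod$from)
  keep <- unique(c(targets, tfs, modulators))
  sub_nodes <- nodes[nodes$gene %in% keep, , drop = FALSE]
  # flags are re-scoped to the subnetwork's own layers
  sub_nodes$target <- sub_nodes$gene %in% targets
  sub_nodes$tf <- sub_nodes$gene %in% tfs
  sub_nodes$oncogene_modulator <- sub_nodes$oncogene_modulator &
    sub_nodes$gene %in% modulators
  sub_nodes$tsg_modulator <- sub_nodes$tsg_modulator &
    sub_nodes$gene %in% modulators
  edges <- dplyr::bind_rows(mod, reg)
  role_counts <- tibble(
    role = c("oncogenes", "tsgs", "tfs", "targets"),
    n = c(sum(sub_nodes$oncogene_modulator), sum(sub_nodes$tsg_modulator),
          sum(sub_nodes$tf), sum(sub_nodes$target))
  )
  structure(
    list(name = name, nodes = sub_nodes, edges = edges,
         role_counts = role_counts,
         parent_signature = signature),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork '%s'> %d nodes, %d edges\n", x$name, nrow(x$nodes),
              nrow(x$edges)))
  print(x$role_counts)
  invisible(x)
}

#' Gene sharing between two subnetworks
#'
#' @param a,b Two [derive_subnetwork()] results from the same parent network.
#' @return List with `by_role` (tibble of per-role intersection, union and
#'   shared fractions relative to each side) and `n_shared_genes` /
#'   `n_union_genes` over the whole node sets.
#' @export
subnetwork_overlap <- function(a, b) {
  stopifnot(inherits(a, "subnetwork"), inherits(b, "subnetwork"))
  if (!identical(a$parent_signature, b$parent_signature)) {
    abort("subnetworks were derived from different parent networks")
  }
  role_genes <- function(x, role) {
    switch(role,
      oncogenes = x$nodes$gene[x$nodes$oncogene_modulator],
      tsgs = x$nodes$gene[x$nodes$tsg_modulator],
      tfs = x$nodes$gene[x$nodes$tf],
      targets = x$nodes$gene[x$nodes$target]
    )
  }
  roles <- c("oncogenes", "tsgs", "tfs", "targets")
  by_role <- dplyr::bind_rows(lapply(roles, function(r) {
    ga <- role_genes(a, r)
    gb <- role_genes(b, r)
    tibble(
      role = r,
      n_a = length(ga), n_b = length(gb),
      n_shared = length(intersect(ga, gb)),
      n_union = length(union(ga, gb)),
      frac_of_a = if (length(ga) > 0) length(intersect(ga, gb)) / length(ga) else NA_real_,
      frac_of_b = if (length(gb) > 0) length(intersect(ga, gb)) / length(gb) else NA_real_
    )
  }))
  list(
    by_role = by_role,
    n_shared_genes = length(intersect(a$nodes$gene, b$nodes$gene)),
    n_union_genes = length(union(a$nodes$gene, b$nodes$gene))
  )
}
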