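#' Binary regulation profile of modulators
#'
#' Rows are modulators, columns are TFs (`axis = "tf"`, direct regulation) or
#' targets (`axis = "target"`, indirect regulation via TFs); an entry is 1
#' exactly when a supporting motif exists. Rows and columns are sorted
#' lexicographically, making the profile deterministic and invariant to motif
#' row order. A modulator without any motif cannot occur (motifs define the
#' rows), so no all-zero rows arise.
#'
#' @param motifs A non-empty [triplet_set()].
#' @param axis `"tf"` or `"target"`.
#' @return A 0/1 integer matrix of class `target_profile` with attribute
#'   `axis`.
#' @export
build_profile <- function(motifs, axis = c("tf", "target")) {
  axis <- match.arg(axis)
  stopifnot(inherits(motifs, "triplet_set"))
  if (nrow(motifs) == 0) abort("cannot build a profile from an empty motif set")
  col <- if (axis == "tf") motifs$tf else motifs$target
  rows <- sort(unique(motifs$modulator))
  cols <- sort(unique(col))
  mat <- matrix(0L, nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
  mat[cbind(match(motifs$modulator, rows), match(col, cols))] <- 1L
  structure(mat, axis = axis, class = c("target_profile", "matrix", "array"))
}

#' Cluster a binary regulation profile
#'
#' Agglomerative clustering of modulator rows under Jaccard (default; the
#' natural distance for sparse 0/1 profiles) or Hamming distance, with
#' average or complete linkage. `stats::hclust` merges are deterministic
#' given the input order, with ties resolved toward the smallest cluster
#' index.
#'
#' @param profile A [build_profile()] matrix.
#' @param distance `"jaccard"` or `"hamming"`.
#' @param linkage `"average"` or `"complete"`.
#' @param k Number of flat clusters to cut (default 2, the
#'   oncogene-versus-TSG question).
#' @return List with `hclust` (the dendrogram), `clusters` (named integer
#'   vector from [stats::cutree()]), `leaf_order` (row names in dendrogram
#'   leaf order) and `distance`/`linkage`.
#' @export
cluster_profile <- function(profile, distance = c("jaccard", "hamming"),
                            linkage = c("average", "complete"), k = 2) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(inherits(profile, "target_profile") || is.matrix(profile))
  if (nrow(profile) < 2) abort("need at least 2 rows to cluster")
  if (nrow(unique(profile)) == 1) inform("all rows identical: a single cluster")
  d <- switch(distance,
    jaccard = vegan::vegdist(profile, method = "jaccard", binary = TRUE),
    hamming = stats::dist(profile, method = "manhattan") / ncol(profile)
  )
  # disjoint all-zero rows make Jaccard 0/0; treat as maximally distant
  d[is.na(d)] <- 1
  hc <- hclust(as.dist(d), method = linkage)
  clusters <- cutree(hc, k = min(k, nrow(profile)))
  list(hclust = hc, clusters = clusters,
       leaf_order = rownames(profile)[hc$order],
       distance = distance, linkage = linkage)
}

#' Long-format dot-plot data for a regulation profile
#'
#' One record per 1-entry of the profile; all-zero columns do not appear.
#' Rows are ordered by dendrogram leaf order (computed with the default
#' clustering when not supplied), the order a dot plot should display.
#'
#' @param profile A [build_profile()] matrix.
#' @param leaf_order Optional character vector of row names in display
#'   order.
#' @return Tibble with columns `modulator`, `gene`, `value` (all 1), with
#'   `modulator` and `gene` as factors in display order.
#' @export
dotplot_data <- function(profile, leaf_order = NULL) {
  stopifnot(inherits(profile, "target_profile") || is.matrix(profile))
  if (is.null(leaf_order)) {
    leaf_order <- if (nrow(profile) >= 2) {
      cluster_profile(profile)$leaf_order
    } else {
      rownames(profile)
    }
  }
  idx <- which(profile == 1L, arr.ind = TRUE)
  out <- tibble(
    modulator = rownames(profile)[idx[, 1]],
    gene = colnames(profile)[idx[, 2]],
    value = 1L
  )
  out$modulator <- factor(out$modulator, levels = leaf_order)
  out$gene <- factor(out$gene, levels = sort(unique(out$gene)))
  dplyr::arrange(out, .data$modulator, .data$gene)
}

#' Dot plot of a regulation profile
#'
#' @param object A [build_profile()] matrix.
#' @param ... Passed to [dotplot_data()].
#' @return A ggplot object.
#' @method autoplot target_profile
#' @export
autoplot.target_profile <- function(object, ...) {
  dat <- dotplot_data(object, ...)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene, y = .data$modulator)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(
      x = if (attr(object, "axis") == "tf") "transcription factor" else "target gene",
      y = "modulator"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}
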