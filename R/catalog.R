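#' Build a gene-role catalog
#'
#' Maps role source lists (transcription factors, oncogenes, tumour suppressor
#' genes) onto a disease gene list and the expression universe. The mapped
#' roles define the candidate positions of a regulatory triplet: modulators
#' are the mapped oncogenes and TSGs, TFs the mapped transcription factors,
#' and any universe gene may serve as a target. Roles may overlap — a gene can
#' simultaneously be TF, oncogene and TSG, and overlap is preserved, never
#' resolved by priority, because downstream loop and multi-role analyses
#' depend on it.
#'
#' @param disease Character vector of disease-associated gene symbols (may be
#'   `NULL` to skip the disease intersection).
#' @param tf_source,ocg_source,tsg_source Source role lists.
#' @param universe Genes present in the expression data.
#' @return An object of class `gene_catalog`: a list with elements `tfs`,
#'   `oncogenes`, `tsgs`, `modulators`, `universe`, `disease` and a `report`
#'   tibble of intersection sizes.
#' @examples
#' build_catalog(
#'   disease = c("A", "B", "C"), tf_source = "B", ocg_source = "A",
#'   tsg_source = "C", universe = c("A", "B", "C", "D")
#' )
#' @export
build_catalog <- function(disease, tf_source, ocg_source, tsg_source, universe) {
  stopifnot(length(tf_source) > 0, length(ocg_source) > 0,
            length(tsg_source) > 0, length(universe) > 0)
  universe <- unique(as.character(universe))
  clip <- function(x) {
    x <- unique(as.character(x))
    if (!is.null(disease)) x <- intersect(x, disease)
    intersect(x, universe)
  }
  tfs <- clip(tf_source)
  oncogenes <- clip(ocg_source)
  tsgs <- clip(tsg_source)
  modulators <- union(oncogenes, tsgs)
  if (length(modulators) == 0) abort("no modulators survive the intersection; inference impossible")
  if (length(tfs) == 0) abort("no TFs survive the intersection; inference impossible")
  report <- tibble(
    set = c("disease", "universe", "tfs", "oncogenes", "tsgs", "modulators"),
    n = c(length(disease %||% character()), length(universe), length(tfs),
          length(oncogenes), length(tsgs), length(modulators))
  )
  structure(
    list(disease = disease %||% character(), tfs = tfs, oncogenes = oncogenes,
         tsgs = tsgs, modulators = modulators, universe = universe,
         report = report),
    class = "gene_catalog"
  )
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("<gene_catalog>\n")
  print(x$report)
  invisible(x)
}

#' Candidate triplet space implied by a catalog
#'
#' Every ordered combination of a modulator, a TF and a universe gene is a
#' candidate triplet, provided the three are pairwise distinct. Role genes are
#' not excluded from targethood.
#'
#' @param catalog A `gene_catalog`.
#' @return List with `tfs`, `modulators`, `targets` (the whole universe) and
#'   `n_triples`, the number of admissible (modulator, tf, target)
#'   combinations.
#' @export
candidate_space <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  u <- catalog$universe
  n <- 0
  for (m in catalog$modulators) {
    for (f in catalog$tfs) {
      if (m == f) next
      n <- n + length(u) - length(unique(c(m, f)))
    }
  }
  list(tfs = catalog$tfs, modulators = catalog$modulators, targets = u,
       n_triples = n)
}
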