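#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for enrichment of the query set against an
#' explicit background universe. For a background of `N` genes containing a
#' term of size `K` and a query of size `n` overlapping the term in `k`
#' genes, the p-value is the upper tail `P[X >= k]` of the
#' hypergeometric(N, K, n) distribution (including the observed `k`);
#' q-values are Benjamini-Hochberg over all tested terms. Query genes
#' outside the background are dropped (a message reports the count), and
#' every term is intersected with the background before testing.
#'
#' @param query Character vector of gene symbols.
#' @param terms A [read_gmt()] map, or a named list of gene-symbol vectors.
#' @param background Character vector: the gene universe.
#' @return Tibble of class `enrichment_result`, sorted by p-value (ties by
#'   term id): `term`, `description`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`.
#' @examples
#' ora(query = c("A", "B"), terms = list(S1 = c("A", "B", "C")),
#'     background = LETTERS[1:20])
#' @export
ora <- function(query, terms, background) {
  background <- unique(as.character(background))
  if (length(background) == 0) abort("background must be non-empty")
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    inform(sprintf("%d query gene(s) outside the background were dropped",
                   length(outside)))
  }
  query <- intersect(query, background)
  if (length(terms) == 0) abort("no terms to test")
  res <- dplyr::bind_rows(lapply(names(terms), function(id) {
    t <- terms[[id]]
    genes <- if (is.list(t)) t$genes else t
    desc <- if (is.list(t)) t$description else NA_character_
    genes <- intersect(unique(genes), background)
    k <- length(intersect(query, genes))
    tibble(
      term = id, description = desc %||% NA_character_,
      k = k, K = length(genes), n = length(query), N = length(background),
      p_value = phyper(k - 1, length(genes), length(background) - length(genes),
                       length(query), lower.tail = FALSE)
    )
  }))
  res$q_value <- bh_adjust(res$p_value)
  res <- dplyr::arrange(res, .data$p_value, .data$term)
  class(res) <- c("enrichment_result", class(tibble()))
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: `q_(i) = min_{j >= i} m p_(j) / j`,
#' capped at 1, returned in the input order. A thin validating wrapper over
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return The result as a plain tibble.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' Enrichment bar chart
#'
#' @param object An `enrichment_result`.
#' @param max_terms Show at most this many top terms.
#' @param ... Unused.
#' @return A ggplot object of `-log10(q)` per term.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, max_terms = 20, ...) {
  dat <- head(object, max_terms)
  dat$term <- factor(dat$term, levels = rev(dat$term))
  ggplot2::ggplot(dat, ggplot2::aes(x = -log10(.data$q_value), y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "BH q-value"), y = NULL) +
    ggplot2::theme_minimal()
}
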