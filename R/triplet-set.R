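#' Construct a triplet set
#'
#' A triplet set is the unit of exchange of the whole pipeline: a tibble with
#' one row per regulatory motif `(modulator, tf, target)` plus its score (the
#' conditional mutual information difference, in the units recorded in the
#' attached parameters) and its sign call. Rows are keyed by the three gene
#' symbols; keys must be unique and the three symbols of a row pairwise
#' distinct.
#'
#' @param modulator,tf,target Character vectors of gene symbols.
#' @param score Numeric scores, finite.
#' @param sign `"positive"` or `"negative"` per row; positive means the
#'   modulator enhances the TF-target dependence.
#' @param cohort Optional cohort identifier attached as an attribute.
#' @param params Optional [inference_params()] attached as an attribute.
#' @return A tibble of class `triplet_set` with columns `modulator`, `tf`,
#'   `target`, `score`, `sign`.
#' @examples
#' triplet_set(modulator = "KRAS", tf = "STAT5B", target = "DOK2", score = 0.25)
#' @export
triplet_set <- function(modulator = character(), tf = character(),
                        target = character(), score = numeric(),
                        sign = rep("positive", length(score)),
                        cohort = NULL, params = NULL) {
  out <- tibble(
    modulator = as.character(modulator),
    tf = as.character(tf),
    target = as.character(target),
    score = as.numeric(score),
    sign = as.character(sign)
  )
  new_triplet_set(out, cohort = cohort, params = params)
}

# Internal validating constructor working from a conforming data frame.
new_triplet_set <- function(df, cohort = NULL, params = NULL) {
  df <- as_tibble(df)[, c("modulator", "tf", "target", "score", "sign")]
  if (nrow(df) > 0) {
    bad <- df$modulator == df$tf | df$modulator == df$target | df$tf == df$target
    if (any(bad)) {
      abort(sprintf(
        "triplet symbols must be pairwise distinct; offending row(s): %s",
        paste(which(bad), collapse = ", ")
      ))
    }
    if (any(!nzchar(df$modulator)) || any(!nzchar(df$tf)) || any(!nzchar(df$target))) {
      abort("gene symbols must be non-empty")
    }
    if (any(!is.finite(df$score))) abort("triplet scores must be finite")
    keys <- triplet_key(df$modulator, df$tf, df$target)
    if (anyDuplicated(keys)) {
      abort("duplicate (modulator, tf, target) keys in triplet set")
    }
    if (!all(df$sign %in% c("positive", "negative"))) {
      abort("sign must be 'positive' or 'negative'")
    }
  }
  structure(df,
    class = c("triplet_set", class(tibble())),
    cohort = cohort, params = params
  )
}

#' @export
print.triplet_set <- function(x, ...) {
  cohort <- attr(x, "cohort")
  cat(sprintf(
    "<triplet_set> %d motif(s)%s\n", nrow(x),
    if (!is.null(cohort)) paste0(" [cohort: ", cohort, "]") else ""
  ))
  NextMethod()
}

# dplyr and [ operations drop to plain tibbles readily; keys() gives the
# canonical identity used for set algebra across cohorts.
triplet_keys <- function(x) triplet_key(x$modulator, x$tf, x$target)

#' Summarise a triplet set
#'
#' @param x A `triplet_set`.
#' @param ... Unused.
#' @return One-row tibble with motif and unique-gene counts per layer.
#' @method glance triplet_set
#' @export
glance.triplet_set <- function(x, ...) {
  tibble(
    n_motifs = nrow(x),
    n_modulators = dplyr::n_distinct(x$modulator),
    n_tfs = dplyr::n_distinct(x$tf),
    n_targets = dplyr::n_distinct(x$target),
    cohort = attr(x, "cohort") %||% NA_character_
  )
}
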