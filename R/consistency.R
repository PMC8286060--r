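#' Cross-cohort consistency rule
#'
#' @param mode `"reference_plus_any"` (a reference motif is kept when at least
#'   one validation cohort also calls it; the default, and the weakest reading
#'   of pairwise reference-vs-validation comparisons), `"reference_plus_k"`
#'   (at least `k` validation cohorts) or `"all_cohorts"` (every validation
#'   cohort).
#' @param k Support count for `reference_plus_k`.
#' @return A list of class `consistency_rule`.
#' @export
consistency_rule <- function(mode = c("reference_plus_any", "reference_plus_k",
                                      "all_cohorts"), k = 1) {
  mode <- match.arg(mode)
  if (k < 1 || k != floor(k)) abort("k must be a positive integer")
  structure(list(mode = mode, k = as.integer(k)), class = "consistency_rule")
}

#' Intersect per-cohort triplet sets into the consistent motif set
#'
#' Membership is decided purely on the `(modulator, tf, target)` key; scores
#' of retained motifs are the reference cohort's (the reference anchors the
#' final network), and each retained motif carries the ids of the validation
#' cohorts supporting it.
#'
#' @param reference [triplet_set()] from the reference cohort.
#' @param validations Non-empty list of validation [triplet_set()]s, named if
#'   possible.
#' @param rule A [consistency_rule()].
#' @return A [triplet_set()] (subset of `reference`) with an extra
#'   `supporting_cohorts` list-column and `n_support` count column.
#' @export
consistent_motifs <- function(reference, validations,
                              rule = consistency_rule()) {
  stopifnot(inherits(reference, "triplet_set"))
  if (!is.list(validations) || length(validations) == 0) {
    abort("at least one validation triplet set is required")
  }
  if (is.null(names(validations)) || any(!nzchar(names(validations)))) {
    names(validations) <- vapply(seq_along(validations), function(i) {
      attr(validations[[i]], "cohort") %||% paste0("validation", i)
    }, character(1))
  }
  ref_theta <- attr(reference, "params")$theta
  for (nm in names(validations)) {
    v_theta <- attr(validations[[nm]], "params")$theta
    if (!is.null(ref_theta) && !is.null(v_theta) && v_theta != ref_theta) {
      warn(sprintf("validation set '%s' used theta = %g but reference used %g",
                   nm, v_theta, ref_theta))
    }
  }
  rk <- triplet_keys(reference)
  support <- lapply(validations, function(v) rk %in% triplet_keys(v))
  n_support <- Reduce(`+`, lapply(support, as.integer))
  need <- switch(rule$mode,
    reference_plus_any = 1L,
    reference_plus_k = {
      if (rule$k > length(validations)) {
        abort(sprintf("k = %d exceeds the %d validation cohorts", rule$k,
                      length(validations)))
      }
      rule$k
    },
    all_cohorts = length(validations)
  )
  keep <- n_support >= need
  out <- as_tibble(reference)[keep, , drop = FALSE]
  out$n_support <- n_support[keep]
  out$supporting_cohorts <- lapply(which(keep), function(i) {
    names(validations)[vapply(support, `[`, logical(1), i)]
  })
  res <- new_triplet_set(out, cohort = attr(reference, "cohort"),
                         params = attr(reference, "params"))
  res$n_support <- out$n_support
  res$supporting_cohorts <- out$supporting_cohorts
  attr(res, "rule") <- rule
  res
}

#' Summarise a consistency run
#'
#' Counts the unique genes per layer of the consistent set, splits modulators
#' into oncogenes and TSGs when a catalog is supplied, and reports the size
#' of the overlap between the reference and each validation cohort.
#'
#' @param reference,validations As in [consistent_motifs()].
#' @param result The [consistent_motifs()] output (must be a subset of
#'   `reference`).
#' @param catalog Optional [build_catalog()] object for the oncogene/TSG
#'   split.
#' @return List with `counts` (one-row tibble) and `per_validation` (tibble
#'   of pairwise overlap sizes).
#' @export
consistency_report <- function(reference, validations, result, catalog = NULL) {
  stopifnot(inherits(result, "triplet_set"))
  if (!all(triplet_keys(result) %in% triplet_keys(reference))) {
    abort("result must be a subset of the reference set")
  }
  n_ocg <- n_tsg <- NA_integer_
  if (!is.null(catalog)) {
    mods <- unique(result$modulator)
    n_ocg <- length(intersect(mods, catalog$oncogenes))
    n_tsg <- length(intersect(mods, catalog$tsgs))
  }
  counts <- tibble(
    n_motifs = nrow(result),
    n_tfs = dplyr::n_distinct(result$tf),
    n_modulators = dplyr::n_distinct(result$modulator),
    n_oncogenes = n_ocg,
    n_tsgs = n_tsg,
    n_targets = dplyr::n_distinct(result$target)
  )
  rk <- triplet_keys(reference)
  if (is.null(names(validations))) names(validations) <- paste0("validation", seq_along(validations))
  per_val <- tibble(
    cohort = names(validations),
    n_called = vapply(validations, nrow, integer(1)),
    n_overlap_reference = vapply(validations, function(v) {
      sum(rk %in% triplet_keys(v))
    }, integer(1))
  )
  list(counts = counts, per_validation = per_val)
}
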