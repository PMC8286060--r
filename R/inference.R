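#' Inference parameters
#'
#' Bundles the tuning knobs of triplet scoring. `q` is the conditioning
#' fraction: the top and bottom `ceiling(q * n)` samples by modulator
#' expression form the high- and low-modulator strata. `bins` controls the
#' equal-frequency discretization used by the plug-in mutual information
#' estimator. `theta` is the positive-call threshold on the conditional MI
#' difference, in `mi_units`; the conventional default is 0.1. Strata smaller
#' than `min_stratum` are refused, and modulators whose interquartile range
#' does not exceed `modulator_min_iqr` are skipped (an expression-less
#' modulator cannot stratify anything).
#'
#' @param q Conditioning fraction in (0, 0.5].
#' @param bins Number of discretization bins, integer >= 2.
#' @param theta Positive-call threshold on the score, >= 0.
#' @param min_stratum Minimum samples per stratum.
#' @param modulator_min_iqr Minimum (exclusive) modulator IQR.
#' @param mi_units `"bits"` (log base 2) or `"nats"` (natural log).
#' @return A list of class `inference_params`.
#' @export
inference_params <- function(q = 0.35, bins = 4, theta = 0.1, min_stratum = 20,
                             modulator_min_iqr = 0, mi_units = c("bits", "nats")) {
  mi_units <- match.arg(mi_units)
  if (!is.numeric(q) || q <= 0 || q > 0.5) abort("q must lie in (0, 0.5]")
  if (bins < 2 || bins != floor(bins)) abort("bins must be an integer >= 2")
  if (theta < 0) abort("theta must be >= 0")
  if (min_stratum < 2) abort("min_stratum must be >= 2")
  structure(
    list(q = q, bins = as.integer(bins), theta = theta,
         min_stratum = as.integer(min_stratum),
         modulator_min_iqr = modulator_min_iqr, mi_units = mi_units),
    class = "inference_params"
  )
}

#' Equal-frequency discretization
#'
#' Assigns each value to one of `bins` rank bins whose sizes differ by at most
#' one. Ties are broken by stable input order, so the labelling is fully
#' deterministic and invariant under strictly monotone transformations of the
#' values.
#'
#' @param values Numeric vector, length >= `bins`.
#' @param bins Number of bins.
#' @return Integer vector of bin labels in `1:bins`.
#' @examples
#' discretize(c(5, 1, 4, 2, 3, 6), bins = 2)
#' @export
discretize <- function(values, bins) {
  n <- length(values)
  if (bins < 2 || bins != floor(bins)) abort("bins must be an integer >= 2")
  if (n < bins) abort(sprintf("need at least %d values for %d bins", bins, bins))
  if (length(unique(values)) == 1L) {
    warn("constant vector: all samples land in a single bin")
    return(rep(1L, n))
  }
  .discretize(values, as.integer(bins))
}

# Internal fast path: no validation, no constant-vector warning.
.discretize <- function(values, bins) {
  n <- length(values)
  ord <- order(values)             # radix sort, stable in ties
  out <- integer(n)
  out[ord] <- ((seq_len(n) - 1L) * bins) %/% n + 1L
  out
}

# Plug-in MI from two label vectors over 1:bins each; nats unless bits.
.mi_labels <- function(lx, ly, bins, bits = TRUE) {
  n <- length(lx)
  joint <- tabulate((lx - 1L) * bins + ly, nbins = bins * bins)
  px <- tabulate(lx, nbins = bins)
  py <- tabulate(ly, nbins = bins)
  nz <- which(joint > 0L)
  cj <- joint[nz]
  i <- (nz - 1L) %/% bins + 1L
  j <- nz - (i - 1L) * bins
  mi <- sum(cj * log(cj * n / (px[i] * py[j]))) / n
  mi <- max(mi, 0)
  if (bits) mi / log(2) else mi
}

#' Plug-in mutual information on discretized vectors
#'
#' Discretizes `x` and `y` by equal-frequency binning and returns the plug-in
#' estimate `sum_ij p_ij log(p_ij / (p_i p_j))` over the joint contingency
#' table. The estimate is zero exactly when the empirical table factorizes,
#' and is clamped at zero (the plug-in sum cannot be negative analytically,
#' but floating point can dip below by rounding).
#'
#' @param x,y Numeric vectors of equal length, at least `2 * bins`.
#' @param bins Number of bins per axis.
#' @param units `"bits"` or `"nats"`.
#' @return Non-negative scalar MI estimate.
#' @export
mutual_information <- function(x, y, bins = 4, units = c("bits", "nats")) {
  units <- match.arg(units)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2 * bins) abort("need at least 2 * bins samples")
  .mi_labels(.discretize(x, as.integer(bins)), .discretize(y, as.integer(bins)),
             as.integer(bins), bits = units == "bits")
}

# Stratum index sets: top and bottom ceiling(q * n) samples by m.
.strata <- function(m, params) {
  n <- length(m)
  k <- ceiling(params$q * n)
  if (2 * k > n) abort("2 * ceiling(q * n) exceeds the sample size; lower q")
  if (k < params$min_stratum) {
    abort(sprintf(
      "stratum size %d is below min_stratum = %d; need a cohort of >= %d samples at q = %g",
      k, params$min_stratum, ceiling(params$min_stratum / params$q), params$q
    ))
  }
  ord <- order(m)
  list(low = ord[seq_len(k)], high = ord[seq.int(n - k + 1L, n)], k = k)
}

#' Conditional mutual information difference for one triplet
#'
#' The triplet score: samples are split into a high- and a low-modulator
#' stratum (top and bottom `ceiling(q * n)` by modulator expression, ties
#' stable), TF and target are discretized within each stratum separately, and
#' the score is `MI(tf, target | m high) - MI(tf, target | m low)`. A positive
#' score means the modulator enhances the TF-target statistical dependence.
#'
#' @param m,tf,t Numeric expression vectors of equal length (modulator, TF,
#'   target).
#' @param params An [inference_params()].
#' @return Scalar score in `params$mi_units`.
#' @export
delta_i <- function(m, tf, t, params = inference_params()) {
  if (length(m) != length(tf) || length(m) != length(t)) {
    abort("m, tf and t must have equal length")
  }
  st <- .strata(m, params)
  bins <- params$bins
  bits <- params$mi_units == "bits"
  hi <- .mi_labels(.discretize(tf[st$high], bins), .discretize(t[st$high], bins),
                   bins, bits)
  lo <- .mi_labels(.discretize(tf[st$low], bins), .discretize(t[st$low], bins),
                   bins, bits)
  hi - lo
}

#' Score all candidate triplets of a cohort
#'
#' Runs [delta_i()] over every admissible (modulator, TF, target) combination
#' from [candidate_space()] and returns the positive calls: triplets whose
#' score reaches `params$theta`. Scores are identical to the naive triple
#' loop; the implementation merely shares the per-modulator stratification and
#' per-stratum discretization across pairs. Modulators failing the IQR filter
#' are skipped (a message reports how many).
#'
#' @param expr Expression matrix, genes x samples.
#' @param catalog A [build_catalog()] result; role genes must be rows of
#'   `expr`.
#' @param params An [inference_params()].
#' @param cohort Optional cohort id attached to the result.
#' @param keep_negative Also return triplets with score `<= -theta`, flagged
#'   `sign = "negative"`.
#' @param restrict Optional list with any of `modulators`, `tfs`, `targets`:
#'   restricts the candidate space to these symbols.
#' @return A [triplet_set()] with `params` and `cohort` attributes, ordered by
#'   modulator, TF, target.
#' @export
infer_triplets <- function(expr, catalog, params = inference_params(),
                           cohort = NULL, keep_negative = FALSE,
                           restrict = NULL) {
  stopifnot(is.matrix(expr), inherits(catalog, "gene_catalog"))
  genes <- rownames(expr)
  missing_roles <- setdiff(c(catalog$modulators, catalog$tfs), genes)
  if (length(missing_roles) > 0) {
    abort(sprintf("role gene(s) absent from expression matrix: %s",
                  paste(head(missing_roles, 5), collapse = ", ")))
  }
  mods <- catalog$modulators
  tfs <- catalog$tfs
  targets <- intersect(catalog$universe, genes)
  if (!is.null(restrict)) {
    if (!is.null(restrict$modulators)) mods <- intersect(mods, restrict$modulators)
    if (!is.null(restrict$tfs)) tfs <- intersect(tfs, restrict$tfs)
    if (!is.null(restrict$targets)) targets <- intersect(targets, restrict$targets)
  }
  if (length(mods) == 0 || length(tfs) == 0 || length(targets) == 0) {
    abort("empty candidate space after restriction")
  }
  iqr <- apply(expr[mods, , drop = FALSE], 1, IQR)
  pass <- iqr > params$modulator_min_iqr
  if (!any(pass)) abort("no modulator passes the IQR filter")
  if (any(!pass)) {
    inform(sprintf("%d modulator(s) failed the IQR filter and were skipped",
                   sum(!pass)))
  }
  mods <- mods[pass]

  bins <- params$bins
  bits <- params$mi_units == "bits"
  pair_genes <- union(tfs, targets)
  acc <- vector("list", length(mods))
  for (mi_idx in seq_along(mods)) {
    m <- mods[mi_idx]
    st <- .strata(expr[m, ], params)
    # per-stratum label matrix for every gene that can appear in a pair
    lab_hi <- t(apply(expr[pair_genes, st$high, drop = FALSE], 1, .discretize, bins))
    lab_lo <- t(apply(expr[pair_genes, st$low, drop = FALSE], 1, .discretize, bins))
    rows <- list()
    for (f in tfs) {
      if (f == m) next
      lfh <- lab_hi[f, ]
      lfl <- lab_lo[f, ]
      ts <- targets[targets != m & targets != f]
      sc <- vapply(ts, function(tg) {
        .mi_labels(lfh, lab_hi[tg, ], bins, bits) -
          .mi_labels(lfl, lab_lo[tg, ], bins, bits)
      }, numeric(1))
      keep <- sc >= params$theta
      if (keep_negative) keep <- keep | sc <= -params$theta
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- tibble(
          modulator = m, tf = f, target = ts[keep], score = unname(sc[keep]),
          sign = ifelse(sc[keep] >= params$theta, "positive", "negative")
        )
      }
    }
    acc[[mi_idx]] <- if (length(rows) > 0) dplyr::bind_rows(rows) else NULL
  }
  out <- dplyr::bind_rows(acc)
  if (nrow(out) == 0) {
    out <- tibble(modulator = character(), tf = character(),
                  target = character(), score = numeric(), sign = character())
  }
  out <- dplyr::arrange(out, .data$modulator, .data$tf, .data$target)
  new_triplet_set(out, cohort = cohort, params = params)
}

#' Permutation null for triplet scores
#'
#' Optional calibration utility: recomputes [delta_i()] under random
#' permutations of the modulator values and returns the empirical upper-tail
#' p-value `(1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams delta_i
#' @param n_perm Number of permutations.
#' @return List with `observed` score and `p_value`.
#' @export
delta_i_permutation <- function(m, tf, t, params = inference_params(),
                                n_perm = 100) {
  obs <- delta_i(m, tf, t, params)
  null <- vapply(seq_len(n_perm), function(i) {
    delta_i(sample(m), tf, t, params)
  }, numeric(1))
  list(observed = obs, p_value = (1 + sum(null >= obs)) / (n_perm + 1))
}
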