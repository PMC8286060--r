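#' Synthetic study configuration
#'
#' Describes a multi-cohort expression study with planted, modulator-gated
#' TF-target dependencies. Defaults mirror the study design the package
#' targets: four cohorts of 180, 100, 40 and 30 samples, 20 planted triplets
#' of which half are shared by every cohort, gate effect `beta = 2`, noise
#' `sigma = 0.5`, and 50 background genes.
#'
#' @param n_background_genes Number of pure-noise background genes.
#' @param n_tfs,n_oncogenes,n_tsgs,n_targets Role pool sizes.
#' @param cohort_sizes Integer vector of per-cohort sample counts.
#' @param n_planted Number of planted triplets (at most `n_targets`; each
#'   planted triplet owns a distinct target gene).
#' @param shared_fraction Fraction of planted triplets active in every
#'   cohort; `floor(shared_fraction * n_planted)` are shared, the rest are
#'   each active in exactly one cohort (round-robin).
#' @param beta Gate effect size (regression weight), > 0.
#' @param sigma Noise standard deviation of planted targets.
#' @param gate `"on_when_high"` (TF drives the target only when the modulator
#'   is above its within-cohort median) or `"on_when_low"`.
#' @param seed Non-negative integer seed; identical seeds give identical
#'   output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_background_genes = 50, n_tfs = 5,
                             n_oncogenes = 5, n_tsgs = 5, n_targets = 20,
                             cohort_sizes = c(180, 100, 40, 30),
                             n_planted = 20, shared_fraction = 0.5,
                             beta = 2, sigma = 0.5,
                             gate = c("on_when_high", "on_when_low"),
                             seed = 1) {
  gate <- match.arg(gate)
  counts <- c(n_background_genes, n_tfs, n_oncogenes, n_tsgs, n_targets,
              cohort_sizes, n_planted)
  if (any(counts <= 0) || any(counts != floor(counts))) {
    abort("all counts and cohort sizes must be positive integers")
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("shared_fraction must lie in [0, 1]")
  }
  if (n_planted > n_targets) {
    abort("n_planted exceeds n_targets: each planted triplet needs its own target gene")
  }
  if (beta < 0) abort("beta must be >= 0")
  if (sigma <= 0) abort("sigma must be > 0")
  if (seed < 0 || seed != floor(seed)) abort("seed must be a non-negative integer")
  structure(
    list(n_background_genes = as.integer(n_background_genes),
         n_tfs = as.integer(n_tfs), n_oncogenes = as.integer(n_oncogenes),
         n_tsgs = as.integer(n_tsgs), n_targets = as.integer(n_targets),
         cohort_sizes = as.integer(cohort_sizes),
         n_planted = as.integer(n_planted), shared_fraction = shared_fraction,
         beta = beta, sigma = sigma, gate = gate, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate multi-cohort expression data with planted triplets
#'
#' Per cohort, every gene is drawn i.i.d. standard normal across samples;
#' then, for each planted triplet active in that cohort, the target gene is
#' overwritten with `beta * g(m) * tf + Normal(0, sigma^2)`, where the gate
#' `g(m)` is 1 when the modulator exceeds its within-cohort median and 0
#' otherwise (reversed for `on_when_low`). Gating therefore switches the
#' TF-target statistical dependence on and off without disturbing marginal
#' means. The first `floor(shared_fraction * n_planted)` triplets in
#' generation order are active in every cohort; the remaining ones are each
#' active in exactly one cohort, assigned round-robin.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohorts` (named list of genes-x-samples matrices),
#'   `catalog` (a [build_catalog()] object over the synthetic universe) and
#'   `planted` (tibble: `modulator`, `tf`, `target`, `beta`, `gate`,
#'   `cohorts` list-column of cohort ids).
#' @examples
#' sim <- generate_cohorts(synthetic_config(cohort_sizes = c(60, 60), seed = 7))
#' names(sim$cohorts)
#' @export
generate_cohorts <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  pad <- function(prefix, k) sprintf("%s%03d", prefix, seq_len(k))
  bg <- pad("BG", config$n_background_genes)
  tfs <- pad("TF", config$n_tfs)
  ocgs <- pad("OCG", config$n_oncogenes)
  tsgs <- pad("TSG", config$n_tsgs)
  tgts <- pad("TGT", config$n_targets)
  genes <- c(bg, tfs, ocgs, tsgs, tgts)
  mods <- c(ocgs, tsgs)
  cohort_ids <- paste0("cohort", seq_along(config$cohort_sizes))

  withr::local_seed(config$seed)

  # planted triplets: cycle modulators and TFs, one distinct target each
  n_p <- config$n_planted
  planted <- tibble(
    modulator = rep_len(mods, n_p),
    tf = rep_len(tfs, n_p),
    target = tgts[seq_len(n_p)],
    beta = config$beta,
    gate = config$gate
  )
  n_shared <- floor(config$shared_fraction * n_p)
  membership <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    membership[[i]] <- if (i <= n_shared) {
      cohort_ids
    } else {
      cohort_ids[(i - n_shared - 1L) %% length(cohort_ids) + 1L]
    }
  }
  planted$cohorts <- membership

  cohorts <- list()
  for (ci in seq_along(cohort_ids)) {
    n <- config$cohort_sizes[ci]
    mat <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                  dimnames = list(genes, sprintf("%s_S%03d", cohort_ids[ci],
                                                 seq_len(n))))
    active <- vapply(membership, function(x) cohort_ids[ci] %in% x, logical(1))
    for (i in which(active)) {
      mv <- mat[planted$modulator[i], ]
      g <- as.numeric(mv > median(mv))
      if (config$gate == "on_when_low") g <- 1 - g
      mat[planted$target[i], ] <-
        config$beta * g * mat[planted$tf[i], ] + rnorm(n, sd = config$sigma)
    }
    cohorts[[cohort_ids[ci]]] <- mat
  }

  catalog <- build_catalog(disease = NULL, tf_source = tfs, ocg_source = ocgs,
                           tsg_source = tsgs, universe = genes)
  list(cohorts = cohorts, catalog = catalog, planted = planted)
}

#' Ground-truth triplet set for one cohort
#'
#' @param planted The `planted` tibble from [generate_cohorts()].
#' @param cohort_id A cohort id occurring in the `cohorts` list-column.
#' @return A [triplet_set()] of the triplets active in that cohort, with the
#'   sentinel score 1.
#' @export
truth_table <- function(planted, cohort_id) {
  all_ids <- unique(unlist(planted$cohorts, use.names = FALSE))
  if (!cohort_id %in% all_ids) {
    abort(sprintf("unknown cohort id '%s' (known: %s)", cohort_id,
                  paste(all_ids, collapse = ", ")))
  }
  active <- vapply(planted$cohorts, function(x) cohort_id %in% x, logical(1))
  p <- planted[active, ]
  triplet_set(modulator = p$modulator, tf = p$tf, target = p$target,
              score = rep(1, nrow(p)), cohort = cohort_id)
}

#' Write a synthetic study to disk
#'
#' Emits one expression TSV per cohort, role list files and per-cohort truth
#' motif tables, in the same formats the readers in this package consume.
#'
#' @param sim A [generate_cohorts()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_study <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (id in names(sim$cohorts)) {
    p <- file.path(dir, paste0(id, "_expression.tsv"))
    mat <- sim$cohorts[[id]]
    lines <- c(paste(c("gene", colnames(mat)), collapse = "\t"),
               paste(rownames(mat),
                     apply(mat, 1, function(v) paste(formatC(v, digits = 8, format = "g"),
                                                     collapse = "\t")),
                     sep = "\t"))
    writeLines(lines, p)
    tt <- truth_table(sim$planted, id)
    pt <- file.path(dir, paste0(id, "_truth_motifs.tsv"))
    write_motif_table(tt, pt)
    paths <- c(paths, p, pt)
  }
  for (role in c("tfs", "oncogenes", "tsgs")) {
    p <- file.path(dir, paste0(role, ".txt"))
    writeLines(sim$catalog[[role]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
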