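#' Run the full triplet-inference pipeline
#'
#' Orchestrates the end-to-end analysis from one configuration: obtain
#' multi-cohort expression data (synthetic, or read from disk), infer
#' triplets per cohort, validate them across cohorts, build and export the
#' hierarchical network, compute topology statistics, regulation profiles
#' and, when a GMT file is configured, function-specific subnetworks and
#' over-representation. Every stage's counts and output-file digests are
#' recorded so that two runs with the same configuration and seed are
#' byte-identical and comparable line by line.
#'
#' @param config A configuration list or the path to a YAML file (see
#'   [read_run_config()]). Recognised keys: `seed`, `outdir`, `synthetic`
#'   (arguments of [synthetic_config()]) or the real-data keys `expression`
#'   (vector of matrix paths, first = reference), `disease_genes`,
#'   `tf_list`, `oncogene_list`, `tsg_list`; `inference` (arguments of
#'   [inference_params()]), `consistency` (arguments of
#'   [consistency_rule()]), `gmt` (path), `topology` (list with `N`,
#'   `metric`).
#' @return An object of class `pipeline_provenance`: list with the config
#'   snapshot, per-stage counts, result objects, output paths and MD5
#'   digests.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% tempfile("tripletnet_run_")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  prov <- list(config = config, seed = seed, outdir = outdir,
               stages = list(), paths = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  # -- data ------------------------------------------------------------------
  dat <- stage("data", {
    if (!is.null(config$synthetic)) {
      sc <- do.call(synthetic_config, c(config$synthetic, list(seed = seed)))
      sim <- generate_cohorts(sc)
      list(cohorts = sim$cohorts, catalog = sim$catalog, planted = sim$planted)
    } else {
      if (is.null(config$expression)) {
        abort("config needs either a 'synthetic' block or 'expression' paths")
      }
      paths <- unlist(config$expression, use.names = FALSE)
      cohorts <- lapply(paths, read_expression_matrix)
      names(cohorts) <- tools::file_path_sans_ext(basename(paths))
      universe <- Reduce(intersect, lapply(cohorts, rownames))
      catalog <- build_catalog(
        disease = if (!is.null(config$disease_genes)) read_gene_list(config$disease_genes) else NULL,
        tf_source = read_gene_list(config$tf_list),
        ocg_source = read_gene_list(config$oncogene_list),
        tsg_source = read_gene_list(config$tsg_list),
        universe = universe
      )
      list(cohorts = cohorts, catalog = catalog, planted = NULL)
    }
  })
  prov$stages$data <- list(
    n_cohorts = length(dat$cohorts),
    cohort_sizes = vapply(dat$cohorts, ncol, integer(1)),
    catalog = dat$catalog$report
  )

  # -- inference per cohort --------------------------------------------------
  params <- do.call(inference_params, config$inference %||% list())
  motif_sets <- stage("inference", {
    sets <- lapply(names(dat$cohorts), function(id) {
      infer_triplets(dat$cohorts[[id]], dat$catalog, params, cohort = id)
    })
    names(sets) <- names(dat$cohorts)
    sets
  })
  for (id in names(motif_sets)) {
    p <- file.path(outdir, paste0("motifs_", id, ".tsv"))
    write_motif_table(motif_sets[[id]], p)
    prov$paths <- c(prov$paths, p)
  }
  prov$stages$inference <- list(
    params = unclass(params),
    n_motifs = vapply(motif_sets, nrow, integer(1))
  )

  # -- consistency -----------------------------------------------------------
  reference_id <- config$reference_cohort %||% names(motif_sets)[1]
  rule <- do.call(consistency_rule, config$consistency %||% list())
  consistent <- stage("consistency", {
    consistent_motifs(motif_sets[[reference_id]],
                      motif_sets[names(motif_sets) != reference_id], rule)
  })
  report <- consistency_report(motif_sets[[reference_id]],
                               motif_sets[names(motif_sets) != reference_id],
                               consistent, dat$catalog)
  p <- file.path(outdir, "consistent_motifs.tsv")
  write_motif_table(consistent, p)
  prov$paths <- c(prov$paths, p)
  prov$stages$consistency <- list(reference = reference_id,
                                  rule = unclass(rule), report = report)

  if (nrow(consistent) == 0) {
    warn("no consistent motifs: downstream stages skipped")
    prov$digests <- tools::md5sum(prov$paths)
    class(prov) <- "pipeline_provenance"
    return(prov)
  }

  # -- network ---------------------------------------------------------------
  network <- stage("network", build_network(consistent, dat$catalog))
  prov$paths <- c(prov$paths, export_network(network, outdir))
  loops <- find_regulatory_loops(network)
  topo_cfg <- config$topology %||% list()
  topo <- stage("topology", {
    cent <- centralities(network)
    role_sets <- list(
      modulators = network$nodes$gene[network$nodes$oncogene_modulator |
                                        network$nodes$tsg_modulator],
      tfs = network$nodes$gene[network$nodes$tf]
    )
    sig <- lapply(role_sets, function(rs) {
      topology_significance(network, rs,
                            metric = topo_cfg$metric %||% "degree",
                            N = topo_cfg$N %||% 499, seed = seed)
    })
    list(centralities = cent, significance = sig)
  })
  prov$stages$network <- list(
    glance = glance(network), n_loops = length(loops),
    multi_role_targets = multi_role_targets(network),
    significance = lapply(topo$significance,
                          function(s) s[c("observed", "p_value", "metric")])
  )
  prov$results <- list(network = network, consistent = consistent,
                       loops = loops, centralities = topo$centralities)

  # -- profiles --------------------------------------------------------------
  profiles <- stage("profiles", {
    lapply(c(tf = "tf", target = "target"), function(ax) {
      pr <- build_profile(consistent, axis = ax)
      cl <- if (nrow(pr) >= 2) cluster_profile(pr) else NULL
      dd <- dotplot_data(pr, leaf_order = if (!is.null(cl)) cl$leaf_order else NULL)
      readr::write_tsv(dd, file.path(outdir, paste0("dotplot_", ax, ".tsv")))
      list(profile = pr, clustering = cl)
    })
  })
  prov$paths <- c(prov$paths, file.path(outdir, c("dotplot_tf.tsv",
                                                  "dotplot_target.tsv")))
  prov$stages$profiles <- lapply(profiles, function(x) dim(x$profile))
  prov$results$profiles <- profiles

  # -- subnetworks + enrichment (optional) -----------------------------------
  if (!is.null(config$gmt)) {
    gmt <- read_gmt(config$gmt)
    subs <- stage("subnetworks", {
      lapply(names(gmt), function(term) {
        derive_subnetwork(network, gmt[[term]]$genes, name = term)
      })
    })
    names(subs) <- names(gmt)
    prov$stages$subnetworks <- lapply(subs, function(s) s$role_counts)
    prov$results$subnetworks <- subs
    enr <- stage("enrichment", {
      ora(query = unique(consistent$target), terms = gmt,
          background = dat$catalog$universe)
    })
    readr::write_tsv(tidy(enr), file.path(outdir, "enrichment.tsv"))
    prov$paths <- c(prov$paths, file.path(outdir, "enrichment.tsv"))
    prov$results$enrichment <- enr
  }

  prov$digests <- tools::md5sum(prov$paths)
  class(prov) <- "pipeline_provenance"
  prov
}

#' @export
print.pipeline_provenance <- function(x, ...) {
  cat("<pipeline_provenance>\n")
  cat(sprintf("  seed: %d   outdir: %s\n", x$seed, x$outdir))
  cat(sprintf("  cohorts: %s\n",
              paste(x$stages$data$cohort_sizes, collapse = "/")))
  cat(sprintf("  motifs per cohort: %s\n",
              paste(x$stages$inference$n_motifs, collapse = ", ")))
  if (!is.null(x$stages$consistency)) {
    cat(sprintf("  consistent motifs: %d\n",
                x$stages$consistency$report$counts$n_motifs))
  }
  invisible(x)
}
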