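# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except through tempfiles written by the tests themselves.

toy_catalog <- function() {
  build_catalog(
    disease = NULL,
    tf_source = c("F1", "F2"),
    ocg_source = c("M1", "Y"),
    tsg_source = c("M2"),
    universe = c("M1", "M2", "F1", "F2", "T1", "T2", "T3", "Y")
  )
}

toy_motifs <- function() {
  triplet_set(
    modulator = c("M1", "M1", "M2", "M2"),
    tf        = c("F1", "F1", "F1", "F2"),
    target    = c("T1", "T2", "T1", "T3"),
    score     = c(0.5, 0.4, 0.3, 0.2)
  )
}

# random motif sets over a synthetic-catalog-shaped gene pool
random_motifs <- function(n, seed) {
  withr::local_seed(seed)
  mods <- paste0("M", 1:4)
  tfs <- paste0("F", 1:3)
  tgts <- paste0("T", 1:6)
  combos <- expand.grid(modulator = mods, tf = tfs, target = tgts,
                        stringsAsFactors = FALSE)
  pick <- combos[sample.int(nrow(combos), n), ]
  triplet_set(pick$modulator, pick$tf, pick$target,
              score = runif(n, 0.1, 1))
}

random_motifs_catalog <- function() {
  build_catalog(NULL, tf_source = paste0("F", 1:3),
                ocg_source = paste0("M", 1:2), tsg_source = paste0("M", 3:4),
                universe = c(paste0("M", 1:4), paste0("F", 1:3), paste0("T", 1:6)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# key strings for truth comparisons
motif_keys <- function(x) paste(x$modulator, x$tf, x$target)

# recall/precision of an inferred set against a truth set
recovery <- function(inferred, truth) {
  ik <- motif_keys(inferred)
  tk <- motif_keys(truth)
  c(recall = mean(tk %in% ik), precision = if (length(ik) > 0) mean(ik %in% tk) else NA_real_)
}

# denser motif pool: large enough that mean node-degree ties (which bias the
# tie-inclusive empirical p upward) carry negligible mass
dense_random_network <- function(n = 300, seed = 1) {
  withr::local_seed(seed)
  mods <- paste0("M", 1:10)
  tfs <- paste0("F", 1:6)
  tgts <- paste0("T", 1:60)
  combos <- expand.grid(modulator = mods, tf = tfs, target = tgts,
                        stringsAsFactors = FALSE)
  pick <- combos[sample.int(nrow(combos), n), ]
  ms <- triplet_set(pick$modulator, pick$tf, pick$target, runif(n, 0.1, 1))
  cat <- build_catalog(NULL, tf_source = tfs, ocg_source = mods[1:5],
                       tsg_source = mods[6:10], universe = c(mods, tfs, tgts))
  build_network(ms, cat)
}
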