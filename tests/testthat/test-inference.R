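test_that("equal-frequency discretization splits by rank with near-equal bins", {
  expect_equal(discretize(c(5, 1, 4, 2, 3, 6), bins = 2),
               c(2L, 1L, 2L, 1L, 1L, 2L))
  lab7 <- discretize(1:7, bins = 2)
  expect_equal(as.integer(table(lab7)), c(4L, 3L))
  # bin sizes never differ by more than one
  for (n in c(9, 10, 11, 23)) {
    sizes <- table(discretize(rnorm(n), bins = 4))
    expect_lte(diff(range(sizes)), 1)
  }
  expect_warning(lab <- discretize(rep(2, 10), bins = 3), "constant")
  expect_equal(unique(lab), 1L)
})

test_that("plug-in MI reproduces hand arithmetic on a fixed contingency table", {
  # labels realise the 2x2 table [[2,1],[1,2]], n = 6
  x <- c(1, 1, 1, 2, 2, 2)
  y <- c(1, 1, 2, 1, 2, 2)
  counts <- c(2, 1, 1, 2)
  p <- counts / 6
  px <- c(0.5, 0.5)
  expected <- sum(p * log2(p / c(px[1] * px[1], px[1] * px[2],
                                 px[2] * px[1], px[2] * px[2])))
  expect_equal(mutual_information(x, y, bins = 2), expected, tolerance = 1e-12)
})

test_that("MI of a variable with itself is one bit for an even two-bin split", {
  x <- rnorm(100)
  expect_equal(mutual_information(x, x, bins = 2), 1, tolerance = 1e-12)
})

test_that("MI estimates are symmetric, non-negative and bounded by log2(bins)", {
  withr::local_seed(42)
  for (i in 1:10) {
    x <- rnorm(60)
    y <- 0.5 * x + rnorm(60)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    expect_gte(mutual_information(x, y), 0)
    expect_lte(mutual_information(x, x, bins = 4), log2(4) + 1e-12)
  }
})

test_that("MI of independent draws is near zero at large n", {
  withr::local_seed(1)
  x <- runif(10000)
  y <- runif(10000)
  expect_lt(mutual_information(x, y, bins = 4), 0.01)
})

test_that("MI rejects mismatched or too-short inputs", {
  expect_error(mutual_information(1:10, 1:9), "equal length")
  expect_error(mutual_information(1:5, 1:5, bins = 4), "samples")
})

test_that("delta_i is exactly antisymmetric under stratum swap", {
  withr::local_seed(8)
  m <- rnorm(200)
  f <- rnorm(200)
  t <- rnorm(200)
  p <- inference_params(min_stratum = 10)
  # negating the modulator swaps the high and low strata exactly
  expect_equal(delta_i(m, f, t, p), -delta_i(-m, f, t, p), tolerance = 1e-12)
})

test_that("delta_i is invariant under strictly monotone transforms of each input", {
  withr::local_seed(9)
  m <- rnorm(300)
  f <- rnorm(300)
  t <- 0.5 * f + rnorm(300)
  p <- inference_params(min_stratum = 20)
  base <- delta_i(m, f, t, p)
  expect_equal(delta_i(exp(m), f, t, p), base)
  expect_equal(delta_i(m, atan(f), t, p), base)
  expect_equal(delta_i(m, f, t^3, p), base)
})

test_that("delta_i detects a planted gate and is quiet under the null", {
  cfg <- synthetic_config(n_background_genes = 1, n_tfs = 1, n_oncogenes = 1,
                          n_tsgs = 1, n_targets = 2, n_planted = 1,
                          shared_fraction = 1, cohort_sizes = 1000,
                          beta = 2, sigma = 0.5, seed = 21)
  sim <- generate_cohorts(cfg)
  m <- sim$cohorts[[1]]
  pl <- sim$planted
  expect_gt(delta_i(m[pl$modulator, ], m[pl$tf, ], m[pl$target, ]), 0.1)
  # TGT002 is pure noise: null score is small
  expect_lt(abs(delta_i(m[pl$modulator, ], m[pl$tf, ], m["TGT002", ])), 0.05)
})

test_that("undersized strata are refused with the cohort size needed", {
  p <- inference_params()  # min_stratum 20
  expect_error(delta_i(rnorm(30), rnorm(30), rnorm(30), p), ">= 58")
})

test_that("triplet scoring recovers planted triplets and respects theta", {
  sim <- generate_cohorts(synthetic_config(cohort_sizes = 1000, seed = 4))
  expr <- sim$cohorts[[1]]
  ts <- infer_triplets(expr, sim$catalog, cohort = "cohort1")
  rec <- recovery(ts, truth_table(sim$planted, "cohort1"))
  expect_gte(rec["recall"], 0.9)
  expect_true(all(ts$score >= 0.1))
  expect_true(all(ts$sign == "positive"))
  # theta = Inf empties the set; higher theta yields a subset
  empty <- infer_triplets(expr, sim$catalog, inference_params(theta = Inf))
  expect_equal(nrow(empty), 0L)
  stricter <- infer_triplets(expr, sim$catalog, inference_params(theta = 0.3),
                             cohort = "cohort1")
  expect_true(all(motif_keys(stricter) %in% motif_keys(ts)))
})

test_that("triplet scoring is invariant to sample order", {
  sim <- generate_cohorts(synthetic_config(cohort_sizes = 200, seed = 6,
                                           n_background_genes = 5,
                                           n_targets = 5, n_planted = 5))
  expr <- sim$cohorts[[1]]
  perm <- withr::with_seed(1, sample(ncol(expr)))
  a <- infer_triplets(expr, sim$catalog)
  b <- infer_triplets(expr[, perm], sim$catalog)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("candidate restriction narrows the scored space", {
  sim <- generate_cohorts(synthetic_config(cohort_sizes = 200, seed = 6,
                                           n_background_genes = 5,
                                           n_targets = 5, n_planted = 5))
  full <- infer_triplets(sim$cohorts[[1]], sim$catalog)
  one_tf <- infer_triplets(sim$cohorts[[1]], sim$catalog,
                           restrict = list(tfs = "TF001"))
  expect_true(all(one_tf$tf == "TF001"))
  expect_true(all(motif_keys(one_tf) %in% motif_keys(full)))
})

test_that("modulators without spread are filtered, and all-flat input errors", {
  sim <- generate_cohorts(synthetic_config(cohort_sizes = 200, seed = 2,
                                           n_background_genes = 5,
                                           n_targets = 5, n_planted = 5))
  expr <- sim$cohorts[[1]]
  expr[sim$catalog$modulators, ] <- 0  # kill every modulator's spread
  expect_error(infer_triplets(expr, sim$catalog), "IQR filter")
})

test_that("permutation calibration gives small p for a planted triplet", {
  cfg <- synthetic_config(n_background_genes = 1, n_tfs = 1, n_oncogenes = 1,
                          n_tsgs = 1, n_targets = 1, n_planted = 1,
                          shared_fraction = 1, cohort_sizes = 400, seed = 13)
  sim <- generate_cohorts(cfg)
  m <- sim$cohorts[[1]]
  pl <- sim$planted
  withr::local_seed(1)
  res <- delta_i_permutation(m[pl$modulator, ], m[pl$tf, ], m[pl$target, ],
                             inference_params(min_stratum = 10), n_perm = 49)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$observed, 0.1)
})
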