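# wrap an arbitrary igraph in the network container (topology helpers only
# touch $graph)
as_net <- function(g) {
  structure(list(graph = g,
                 nodes = tibble::tibble(gene = igraph::V(g)$name),
                 edges = tibble::tibble()),
            class = "hierarchical_network")
}

test_that("motifs collapse into deduplicated typed edges", {
  one <- triplet_set("M1", "F1", "T1", 0.5)
  cat <- toy_catalog()
  net1 <- build_network(one, cat)
  expect_equal(nrow(net1$nodes), 3L)
  expect_equal(nrow(net1$edges), 2L)
  # two motifs sharing (modulator, tf): modulation edge deduplicated
  two <- triplet_set(c("M1", "M1"), c("F1", "F1"), c("T1", "T2"), c(0.5, 0.4))
  net2 <- build_network(two, cat)
  expect_equal(nrow(net2$nodes), 4L)
  expect_equal(nrow(net2$edges), 3L)
  expect_equal(net2$edges$n_motifs[net2$edges$type == "modulation"], 2L)
})

test_that("edge counts equal distinct pair counts on random motif sets", {
  cat <- random_motifs_catalog()
  for (s in 1:20) {
    ms <- random_motifs(n = 15, seed = s)
    net <- build_network(ms, cat)
    expect_equal(nrow(net$edges),
                 nrow(unique(cbind(ms$modulator, ms$tf))) +
                   nrow(unique(cbind(ms$tf, ms$target))))
    expect_setequal(net$nodes$gene, unique(c(ms$modulator, ms$tf, ms$target)))
  }
})

test_that("unclassifiable motifs are refused by name", {
  cat <- toy_catalog()
  expect_error(build_network(triplet_set("M1", "T1", "F1", 0.2), cat),
               "not a catalog TF")
  expect_error(build_network(triplet_set("T2", "F1", "T1", 0.2), cat),
               "not a catalog modulator")
})

test_that("reciprocal pairs are found as loops, acyclic layers are not", {
  # Y is an oncogene that is also a target: F2 -> Y (regulation) and
  # Y -> F2 (modulation) close a 2-cycle, the reversible-loop pattern
  cat <- toy_catalog()
  ms <- triplet_set(c("M1", "Y"), c("F2", "F2"), c("Y", "T3"), c(0.3, 0.2))
  net <- build_network(ms, cat)
  loops <- find_regulatory_loops(net)
  expect_length(loops, 1L)
  expect_setequal(loops[[1]], c("F2", "Y"))
  acyclic <- build_network(toy_motifs(), cat)
  expect_length(find_regulatory_loops(acyclic), 0L)
})

test_that("loop enumeration equals brute-force 2-cycle counting on random sets", {
  cat <- random_motifs_catalog()
  for (s in 1:10) {
    ms <- random_motifs(n = 20, seed = 100 + s)
    net <- build_network(ms, cat)
    loops <- find_regulatory_loops(net, max_len = 2)
    e <- unique(net$edges[, c("from", "to")])
    keys <- paste(e$from, e$to)
    rev_keys <- paste(e$to, e$from)
    brute <- sum(keys %in% rev_keys & e$from < e$to)
    expect_length(loops, brute)
  }
})

test_that("multi-role target detection flags exactly the overlapping genes", {
  cat <- toy_catalog()
  ms <- triplet_set(c("M1", "M2"), c("F1", "F2"), c("F2", "Y"), c(0.3, 0.2))
  net <- build_network(ms, cat)
  # F2 is a TF appearing as target; Y is an oncogene-modulator? no - Y only
  # appears as a target here, so only F2 is multi-role
  expect_equal(multi_role_targets(net), "F2")
  disjoint <- build_network(toy_motifs(), cat)
  expect_length(multi_role_targets(disjoint), 0L)
})

test_that("centralities follow the stated conventions on a hand-checked path", {
  g <- igraph::graph_from_literal(A -+ B -+ C)
  cent <- centralities(as_net(g))
  # B sits on the single (A, C) shortest path: 1 / ((n-1)(n-2)) = 0.5
  expect_equal(cent$betweenness[cent$gene == "B"], 0.5)
  # harmonic closeness of A: (1/2) * (1/1 + 1/2) = 0.75; C reaches nothing
  expect_equal(cent$closeness[cent$gene == "A"], 0.75)
  expect_equal(cent$closeness[cent$gene == "C"], 0)
  expect_equal(sum(cent$in_degree), sum(cent$out_degree))
  expect_equal(sum(cent$in_degree), igraph::gsize(g))
})

test_that("a star TF has out-degree k", {
  k <- 7
  cat <- build_catalog(NULL, tf_source = "F", ocg_source = "M", tsg_source = "M2",
                       universe = c("F", "M", "M2", paste0("T", 1:k)))
  ms <- triplet_set(rep("M", k), rep("F", k), paste0("T", 1:k), runif(k, 0.2, 0.9))
  cent <- centralities(build_network(ms, cat))
  expect_equal(cent$out_degree[cent$gene == "F"], k)
  expect_equal(cent$in_degree[cent$gene == "F"], 1L)
})

test_that("betweenness matches exhaustive shortest-path counting on random digraphs", {
  for (s in 1:20) {
    g <- withr::with_seed(s, igraph::sample_gnm(8, 12, directed = TRUE))
    igraph::V(g)$name <- paste0("N", 1:8)
    adj <- lapply(igraph::as_adj_list(g, mode = "out"), as.integer)
    expect_equal(centralities(as_net(g))$betweenness, bf_betweenness(adj, 8),
                 tolerance = 1e-12)
  }
})

test_that("topology significance behaves at its boundary cases", {
  net <- build_network(toy_motifs(), toy_catalog())
  all_nodes <- net$nodes$gene
  res <- topology_significance(net, all_nodes, metric = "degree", N = 100, seed = 1)
  expect_equal(res$p_value, 1)       # every draw ties the observed mean
  cent <- centralities(net)
  top <- cent$gene[which.max(cent$degree)]
  ties <- sum(cent$degree == max(cent$degree))
  # single max-degree node: p bounded by the tie fraction
  res2 <- topology_significance(net, top, metric = "degree", N = 999, seed = 2)
  expect_lte(res2$p_value, (1 + 999 * ties / nrow(cent)) / 1000 + 0.05)
  expect_gt(res2$p_value, 0)
  # deterministic given (seed, N)
  res3 <- topology_significance(net, top, metric = "degree", N = 999, seed = 2)
  expect_identical(res2$p_value, res3$p_value)
  expect_error(topology_significance(net, character(0)), "non-empty")
})

test_that("null role sets give roughly uniform topology p-values", {
  net <- dense_random_network(seed = 77)
  ps <- vapply(1:50, function(i) {
    rs <- withr::with_seed(1000 + i, sample(net$nodes$gene, 10))
    topology_significance(net, rs, metric = "degree", N = 199,
                          seed = 2000 + i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("the rewiring null preserves degree sequences and stays reproducible", {
  net <- build_network(random_motifs(25, seed = 78), random_motifs_catalog())
  rs <- head(net$nodes$gene, 4)
  a <- topology_significance(net, rs, metric = "betweenness", N = 100,
                             seed = 5, null = "rewire")
  b <- topology_significance(net, rs, metric = "betweenness", N = 100,
                             seed = 5, null = "rewire")
  expect_identical(a$p_value, b$p_value)
  expect_gt(a$p_value, 0)
})

test_that("TF in/out degree correlation matches rank arithmetic", {
  # hand-built: 3 TFs with in-degrees (1, 2, 3) and out-degrees (1, 2, 3)
  cat <- build_catalog(NULL, tf_source = paste0("F", 1:3),
                       ocg_source = paste0("M", 1:3), tsg_source = "M9",
                       universe = c(paste0("F", 1:3), paste0("M", 1:3), "M9",
                                    paste0("T", 1:6)))
  ms <- triplet_set(
    modulator = c("M1", "M1", "M2", "M1", "M2", "M3"),
    tf        = c("F1", "F2", "F2", "F3", "F3", "F3"),
    target    = c("T1", "T2", "T3", "T4", "T5", "T6"),
    score     = rep(0.2, 6)
  )
  net <- build_network(ms, cat)
  dc <- degree_correlation(net)
  expect_equal(dc$estimate, 1)
  expect_lt(dc$p_value, 1)
  # rank-correlation arithmetic on a non-trivial pattern
  in_deg <- dc$degrees$in_degree
  out_deg <- dc$degrees$out_degree
  expect_equal(dc$estimate, cor(rank(in_deg), rank(out_deg)))
  # constant in-degrees are degenerate
  ms2 <- triplet_set(rep("M1", 3), paste0("F", 1:3), paste0("T", 1:3), rep(0.2, 3))
  expect_error(degree_correlation(build_network(ms2, cat)), "degenerate")
  expect_error(degree_correlation(net1 <- build_network(ms[1:2, ] |>
    (\(x) triplet_set(x$modulator, x$tf, x$target, x$score))(), cat)),
    "at least 3")
})
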