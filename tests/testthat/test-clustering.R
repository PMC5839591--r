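# Shared-neighbor graph construction, edge weighting, and Louvain
# community detection.

test_that("kNN graph follows the pairwise Spearman distances", {
  # s1 and s2 rank-similar; s3 rank-reversed from both
  vals <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4), c(5, 4, 3, 2, 1))
  em <- expression_matrix(vals, paste0("g", 1:5), c("s1", "s2", "s3"),
                          log_transformed = TRUE)
  g <- build_knn_graph(em, k = 1)
  expect_identical(as.vector(g$neighbors), c(2L, 1L, 2L))
  expect_error(build_knn_graph(em, k = 3), "k must be")
})

test_that("duplicated samples are mutual nearest neighbors at distance 0", {
  set.seed(61)
  vals <- matrix(rnorm(50 * 6), 50, 6)
  vals[, 2] <- vals[, 1]
  em <- expression_matrix(vals, paste0("g", 1:50), paste0("s", 1:6),
                          log_transformed = TRUE)
  g <- build_knn_graph(em, k = 1)
  expect_equal(g$neighbors[1, 1], 2L)
  expect_equal(g$neighbors[1, 2], 1L)
  expect_true(any(g$edges$i == 1 & g$edges$j == 2 & g$edges$mutual))
})

test_that("edge weights follow the hypergeometric overlap tail", {
  # identical neighbor sets {3,4,5} for the pair (1,2), 10 samples:
  # p = 1/C(8,3) = 1/56, weight = log10(56)
  gr <- hand_graph(10, cbind(1, 2), k = 3)
  gr$neighbors <- matrix(3:5, nrow = 3, ncol = 10)
  gr$edges$mutual <- FALSE
  w <- weight_edges(gr)
  expect_equal(w$edges$weight, log10(56), tolerance = 1e-12)

  # disjoint neighbor sets, non-mutual: dropped
  gr$neighbors[, 2] <- 6:8
  expect_equal(nrow(weight_edges(gr)$edges), 0)
  # mutual pairs survive with the positive floor weight
  gr$edges$mutual <- TRUE
  kept <- weight_edges(gr)$edges
  expect_equal(nrow(kept), 1)
  expect_gt(kept$weight, 0)
})

test_that("Louvain recovers canonical partitions with exact modularity", {
  # two disconnected triangles: Q = 2 * (3/6 - (6/12)^2) = 0.5
  tri <- hand_graph(6, rbind(c(1, 2), c(1, 3), c(2, 3),
                             c(4, 5), c(4, 6), c(5, 6)))
  part <- louvain(tri, seed = 1)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(part$labels)), 2)
  expect_equal(length(unique(part$labels[1:3])), 1)

  # a single edge: both nodes in one community, Q = 0
  single <- hand_graph(2, cbind(1, 2))
  p2 <- louvain(single, seed = 1)
  expect_equal(length(unique(p2$labels)), 1)
  expect_equal(p2$modularity, 0)

  # complete K5: one community, matching the brute-force optimum
  k5 <- hand_graph(5, t(combn(5, 2)))
  p3 <- louvain(k5, seed = 1)
  expect_equal(length(unique(p3$labels)), 1)
  best <- brute_force_best_partition(k5)
  expect_equal(p3$modularity, best$q, tolerance = 1e-12)
})

test_that("Louvain attains the brute-force optimum on two small cliques", {
  cliq <- function(nodes) t(combn(nodes, 2))
  gr <- hand_graph(6, rbind(cliq(1:3), cliq(4:6)))
  part <- louvain(gr, seed = 2)
  best <- brute_force_best_partition(gr)
  expect_equal(part$modularity, best$q, tolerance = 1e-12)
  # and recovers larger cliques exactly
  gr2 <- hand_graph(16, rbind(cliq(1:8), cliq(9:16)))
  part2 <- louvain(gr2, seed = 2)
  expect_equal(length(unique(part2$labels)), 2)
  expect_equal(length(unique(part2$labels[1:8])), 1)
  expect_gte(part2$modularity,
             randbias:::modularity_direct(gr2$edges,
                                          seq_len(16)))  # > singletons
})

test_that("reported modularity matches igraph's independent evaluation", {
  co <- generate_cohort(cohort_spec(n_samples = 60, n_genes = 300,
                                    structure = "subclasses",
                                    n_subclasses = 2, de_effect = 2,
                                    de_fraction = 0.3,
                                    per_class_log_hazard = c(0, 0.8),
                                    seed = 67))
  part <- cluster_dataset(co$expression, k = 10, seed = 3)
  e <- part$graph$edges
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$i, to = e$j, weight = e$weight),
    directed = FALSE,
    vertices = data.frame(name = seq_len(part$graph$n_samples)))
  memb <- part$labels[as.integer(igraph::V(ig)$name)] + 1L
  expect_equal(part$modularity, igraph::modularity(ig, memb,
                                                   weights = e$weight),
               tolerance = 1e-9)
})

test_that("an edgeless graph yields singletons with a warning", {
  gr <- hand_graph(4, cbind(1, 2))
  gr$edges <- gr$edges[0, ]
  expect_warning(part <- louvain(gr, seed = 1), "edgeless")
  expect_equal(part$labels, 0:3)
  expect_equal(part$modularity, 0)
})

test_that("clustering recovers planted subclasses and is k-insensitive", {
  co <- generate_cohort(cohort_spec(n_samples = 200, n_genes = 800,
                                    structure = "subclasses",
                                    n_subclasses = 2, de_effect = 2,
                                    de_fraction = 0.3,
                                    per_class_log_hazard = c(0, 1),
                                    seed = 71))
  p30 <- cluster_dataset(co$expression, k = 30, seed = 4)
  expect_gte(adjusted_rand_index(p30$labels, co$truth$subclass), 0.9)
  p15 <- cluster_dataset(co$expression, k = 15, seed = 4)
  expect_gte(adjusted_rand_index(p15$labels, p30$labels), 0.8)
  # null cohorts cluster without error (no structural guarantee)
  con <- generate_cohort(cohort_spec(n_samples = 50, n_genes = 100,
                                     structure = "null", seed = 72))
  expect_s3_class(cluster_dataset(con$expression, k = 8, seed = 1),
                  "ClusterPartition")
})

test_that("adjusted_rand_index behaves at its anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})
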