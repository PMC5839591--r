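# Small programmatic fixtures shared across test files.

# tiny expression matrix with known values
tiny_expr <- function() {
  expression_matrix(matrix(c(1, 2, 3,
                             3, 2, 1,
                             2, 2, 2), nrow = 3, byrow = TRUE),
                    gene_ids = c("gA", "gB", "gC"),
                    sample_ids = c("s1", "s2", "s3"),
                    log_transformed = TRUE)
}

# survival table with ample events
ample_survival <- function(n = 200, seed = 42) {
  with_seed <- randbias:::with_seed
  with_seed(seed, survival_table(sprintf("s%04d", seq_len(n)),
                                 stats::rexp(n, 0.01),
                                 stats::rbinom(n, 1L, 0.9)))
}

# hand-built neighbor graph (bypasses build_knn_graph) for testing
# weighting and Louvain on exactly specified topologies
hand_graph <- function(n, edges, k = 1L, weights = NULL) {
  e <- data.frame(i = edges[, 1L], j = edges[, 2L],
                  weight = if (is.null(weights)) 1 else weights,
                  mutual = TRUE)
  structure(list(sample_ids = sprintf("s%02d", seq_len(n)),
                 neighbors = matrix(0L, nrow = k, ncol = n),
                 edges = e, k = as.integer(k), n_samples = n),
            class = "NeighborGraph")
}

# brute-force maximum-modularity partition by enumerating all set
# partitions of n nodes (feasible for n <= 8)
brute_force_best_partition <- function(graph) {
  n <- graph$n_samples
  labels <- rep(1L, n)
  best <- list(q = -Inf, labels = NULL)
  recurse <- function(i, labels, n_used) {
    if (i > n) {
      q <- randbias:::modularity_direct(graph$edges, labels)
      if (q > best$q) best <<- list(q = q, labels = labels)
      return(invisible())
    }
    for (lab in seq_len(n_used + 1L)) {
      labels[i] <- lab
      recurse(i + 1L, labels, max(n_used, lab))
    }
  }
  recurse(2L, labels, 1L)
  best
}
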