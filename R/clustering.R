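# Data-driven sub-classification in the phenoGraph style: k-nearest
# neighbors under Spearman correlation distance, edges weighted by the
# hypergeometric significance of shared-neighbor overlap, communities by
# Louvain modularity maximization.

#' Build a k-nearest-neighbor graph over samples
#'
#' Pairwise sample distance is 1 - Spearman rho of the gene expression
#' vectors. Each sample's k smallest-distance neighbors are recorded
#' (ties broken by ascending sample index); candidate edges connect
#' every pair where either member lists the other as a neighbor.
#'
#' @param expr an [expression_matrix()].
#' @param k neighbors per sample, `k < n_samples`.
#' @return list of class `NeighborGraph`: `sample_ids`, `neighbors`
#'   (k x n integer matrix, column per sample), `edges` (data frame
#'   `i`, `j`, `weight`, `mutual`; weights `NA` until
#'   [weight_edges()]), `k`, `n_samples`.
#' @export
build_knn_graph <- function(expr, k) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  n <- length(expr$sample_ids)
  if (!is_count(k) || k >= n)
    stop("k must be an integer in [1, n_samples - 1]", call. = FALSE)
  rho <- suppressWarnings(stats::cor(expr$values, method = "spearman"))
  d <- 1 - rho
  nb <- matrix(0L, nrow = k, ncol = n)
  for (i in seq_len(n)) {
    ord <- order(d[, i], seq_len(n))
    ord <- ord[ord != i]
    nb[, i] <- ord[seq_len(k)]
  }
  pairs <- unique(rbind(
    cbind(rep(seq_len(n), each = k), as.vector(nb))))
  lo <- pmin(pairs[, 1L], pairs[, 2L])
  hi <- pmax(pairs[, 1L], pairs[, 2L])
  key <- !duplicated(lo * (n + 1) + hi)
  edges <- data.frame(i = lo[key], j = hi[key], weight = NA_real_)
  is_nb <- function(a, b) b %in% nb[, a]
  edges$mutual <- mapply(function(a, b) is_nb(a, b) && is_nb(b, a),
                         edges$i, edges$j)
  structure(list(sample_ids = expr$sample_ids, neighbors = nb,
                 edges = edges, k = as.integer(k), n_samples = n),
            class = "NeighborGraph")
}

#' Weight graph edges by shared-neighbor overlap significance
#'
#' For each candidate edge (i, j): the overlap of the two neighbor lists
#' (excluding i and j themselves) is scored with the upper
#' hypergeometric tail over a universe of the n - 2 other samples;
#' weight = -log10(p), capped at 300. Edges with zero overlap are
#' dropped unless i and j are mutual nearest neighbors, in which case
#' they are kept with a small positive floor weight (1e-6) so the graph
#' retains its kNN backbone.
#'
#' @param graph a [build_knn_graph()] result.
#' @return the graph with `edges$weight` filled in and non-informative
#'   edges removed.
#' @export
weight_edges <- function(graph) {
  stopifnot(inherits(graph, "NeighborGraph"))
  nb <- graph$neighbors
  n <- graph$n_samples
  e <- graph$edges
  keep <- logical(nrow(e))
  w <- numeric(nrow(e))
  for (r in seq_len(nrow(e))) {
    i <- e$i[r]; j <- e$j[r]
    nb_i <- setdiff(nb[, i], j)
    nb_j <- setdiff(nb[, j], i)
    overlap <- length(intersect(nb_i, nb_j))
    if (overlap == 0L && !e$mutual[r]) next
    p <- hypergeometric_tail(overlap, length(nb_i), length(nb_j), n - 2L)
    w[r] <- min(-log10(p), 300)
    if (w[r] <= 0) w[r] <- 1e-6
    keep[r] <- TRUE
  }
  e$weight <- w
  graph$edges <- e[keep, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

# Direct evaluation of weighted modularity
# Q = sum_c (w_c / W - (d_c / 2W)^2) over communities c, where w_c is
# the total within-community edge weight, d_c the total strength of the
# community's nodes, and W the total edge weight.
modularity_direct <- function(edges, labels) {
  w_tot <- sum(edges$weight)
  if (w_tot == 0) return(0)
  strength <- numeric(length(labels))
  for (r in seq_len(nrow(edges))) {
    strength[edges$i[r]] <- strength[edges$i[r]] + edges$weight[r]
    strength[edges$j[r]] <- strength[edges$j[r]] + edges$weight[r]
  }
  q <- 0
  for (c_ in unique(labels)) {
    members <- which(labels == c_)
    within <- edges$i %in% members & edges$j %in% members
    w_c <- sum(edges$weight[within])
    d_c <- sum(strength[members])
    q <- q + w_c / w_tot - (d_c / (2 * w_tot))^2
  }
  q
}

#' Louvain community detection on a weighted neighbor graph
#'
#' Two-phase Louvain modularity maximization at resolution 1 (via
#' igraph), with the node visit order governed by `seed`. The reported
#' modularity is re-evaluated directly from the modularity formula on
#' the stored graph, independently of the optimizer. An edgeless graph
#' yields singleton communities with modularity 0 and a warning.
#'
#' @param graph a weighted [weight_edges()] graph.
#' @param seed integer seed.
#' @return list of class `ClusterPartition`: `sample_ids`, `labels`
#'   (contiguous integers from 0), `modularity`, `k`, `seed`, and the
#'   `graph` it was computed on.
#' @export
louvain <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "NeighborGraph"))
  e <- graph$edges
  n <- graph$n_samples
  if (!nrow(e)) {
    warning("edgeless graph: every sample its own community",
            call. = FALSE)
    labels <- seq_len(n) - 1L
    return(structure(list(sample_ids = graph$sample_ids, labels = labels,
                          modularity = 0, k = graph$k,
                          seed = as.integer(seed), graph = graph),
                     class = "ClusterPartition"))
  }
  if (any(is.na(e$weight)))
    stop("graph has unweighted edges; run weight_edges() first",
         call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$i, to = e$j, weight = e$weight),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comm <- with_seed(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(comm)[as.character(seq_len(n))]
  labels <- as.integer(factor(memb)) - 1L
  structure(list(sample_ids = graph$sample_ids, labels = labels,
                 modularity = modularity_direct(e, labels),
                 k = graph$k, seed = as.integer(seed), graph = graph),
            class = "ClusterPartition")
}

#' Cluster a dataset into transcriptional sub-classes
#'
#' The full chain [build_knn_graph()] then [weight_edges()] then
#' [louvain()]. The default k is 30 (the customary shared-neighbor
#' default), reduced to floor(n/3) for small cohorts.
#'
#' @param expr an [expression_matrix()].
#' @param k neighbors per sample; default `min(30, floor(n/3))`.
#' @param seed integer seed.
#' @return a `ClusterPartition`.
#' @export
cluster_dataset <- function(expr, k = NULL, seed = 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  n <- length(expr$sample_ids)
  if (is.null(k)) k <- max(1L, min(30L, floor(n / 3)))
  louvain(weight_edges(build_knn_graph(expr, k)), seed = seed)
}

#' @export
print.ClusterPartition <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf(
    "ClusterPartition: %d samples, %d communities (sizes %s), Q = %.3f, k = %d\n",
    length(x$sample_ids), length(sizes),
    paste(as.integer(sizes), collapse = "/"), x$modularity, x$k))
  invisible(x)
}

#' @export
as.data.frame.ClusterPartition <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, cluster = x$labels)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#'
#' @param labels1,labels2 label vectors of equal length.
#' @return the ARI (1 = identical partitions, ~0 = chance agreement).
#' @export
adjusted_rand_index <- function(labels1, labels2) {
  if (length(labels1) != length(labels2))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(labels1, labels2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
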