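# Orchestration: per-dataset bias analysis with and without proliferation
# adjustment, per-cluster re-analysis against size-matched random
# subsamples, clinical-label stratification, and report rendering.

#' Analyze one dataset end to end
#'
#' Runs the random-set bias analysis on the raw expression; when a
#' signature (or an anchor gene to derive one from) is supplied, repeats
#' it on proliferation-adjusted expression; optionally adds the
#' half-split consistency analysis and the clustering arm (partition,
#' per-cluster re-analysis, size-matched subsample controls). All
#' parameters and seeds are recorded in the provenance block, which is
#' sufficient to re-run the report bit-identically.
#'
#' @param expr an [expression_matrix()].
#' @param surv a [survival_table()].
#' @param dataset_label label used in reports.
#' @param set_sizes sizes for the bias sweep (default just 64, the
#'   reporting size; pass `2^(0:10)` for the full sweep).
#' @param set_size the reporting size for per-cluster/consistency work.
#' @param b random sets (and null assignments) per analysis.
#' @param seed master integer seed; all stage seeds derive from it.
#' @param signature optional [gene_list()] proliferation signature.
#' @param anchor optional anchor gene id; when given (and `signature` is
#'   not), the signature is derived in-dataset via
#'   [derive_signature_from_anchor()].
#' @param top_fraction fraction of genes for the anchor-derived
#'   signature.
#' @param run_consistency logical; add [consistency_analysis()]?
#' @param n_splits,sets_per_split consistency parameters.
#' @param run_clustering logical; add the clustering arm?
#' @param k neighbors for [cluster_dataset()] (`NULL` = default rule).
#' @param min_cluster_size smallest cluster analyzed (default 10).
#' @return list of class `DatasetReport`.
#' @export
analyze_dataset <- function(expr, surv, dataset_label = "dataset",
                            set_sizes = 64L, set_size = 64L, b = 1000L,
                            seed = 1L, signature = NULL, anchor = NULL,
                            top_fraction = 0.01,
                            run_consistency = FALSE, n_splits = 50L,
                            sets_per_split = 100L,
                            run_clustering = FALSE, k = NULL,
                            min_cluster_size = 10L) {
  ac <- align_cohort(expr, surv)
  expr <- ac$expr; surv <- ac$surv
  if (!set_size %in% set_sizes) set_sizes <- sort(unique(c(set_sizes,
                                                           set_size)))
  bias_raw <- run_bias_analysis(expr, surv, set_sizes = set_sizes, b = b,
                                seed = seed,
                                dataset_label = dataset_label)

  bias_adjusted <- NULL
  signature_source <- "none"
  if (is.null(signature) && !is.null(anchor)) {
    signature <- derive_signature_from_anchor(expr, anchor, top_fraction)
    signature_source <- sprintf("anchor_derived(%s, top %.3g)", anchor,
                                top_fraction)
  } else if (!is.null(signature)) {
    signature_source <- "user_supplied"
  }
  if (!is.null(signature)) {
    score <- proliferation_score(expr, signature)
    adj <- adjust_expression(expr, score)
    bias_adjusted <- run_bias_analysis(adj$residuals, surv,
                                       set_sizes = set_sizes, b = b,
                                       seed = seed,
                                       dataset_label = dataset_label,
                                       adjusted = TRUE)
  }

  consistency <- NULL
  if (run_consistency)
    consistency <- consistency_analysis(expr, surv, set_size = set_size,
                                        n_splits = n_splits,
                                        sets_per_split = sets_per_split,
                                        seed = derive_seed(seed, 7L))

  partition <- NULL; per_cluster <- list(); subsample <- list()
  if (run_clustering) {
    partition <- cluster_dataset(expr, k = k,
                                 seed = derive_seed(seed, 11L))
    per_cluster <- per_cluster_analysis(expr, surv, partition, b = b,
                                        set_size = set_size,
                                        min_cluster_size =
                                          min_cluster_size,
                                        seed = derive_seed(seed, 13L))
    sizes <- vapply(per_cluster, function(x) x$n_samples, integer(1))
    subsample <- subsample_control(expr, surv, cluster_sizes = sizes,
                                   b = b, set_size = set_size,
                                   seed = derive_seed(seed, 17L))
  }

  structure(list(
    dataset_label = dataset_label,
    n_samples = length(expr$sample_ids), bias_raw = bias_raw,
    bias_adjusted = bias_adjusted, consistency = consistency,
    partition = partition, per_cluster = per_cluster,
    subsample_control = subsample, per_label = NULL,
    provenance = list(
      seed = as.integer(seed), b = as.integer(b),
      set_sizes = as.integer(set_sizes), set_size = as.integer(set_size),
      alpha = 0.05, percentile_rule = "linear interpolation (type 7)",
      log_transformed = expr$log_transformed,
      signature_source = signature_source, anchor = anchor,
      top_fraction = top_fraction, run_consistency = run_consistency,
      n_splits = as.integer(n_splits),
      sets_per_split = as.integer(sets_per_split),
      run_clustering = run_clustering, k = k,
      min_cluster_size = as.integer(min_cluster_size))),
    class = "DatasetReport")
}

#' Re-run the bias analysis inside each cluster
#'
#' Restricts expression and survival to each cluster of at least
#' `min_cluster_size` samples, recomputes the empirical null on the
#' cluster's own survival (the null depends on the survival distribution
#' and group size), and reports a `BiasResult` per cluster. Clusters
#' with no events are skipped with a warning.
#'
#' @param expr,surv the full cohort.
#' @param partition a `ClusterPartition` over the cohort's samples.
#' @param b random sets (and null assignments) per cluster.
#' @param set_size genes per random set.
#' @param min_cluster_size smallest cluster analyzed (default 10).
#' @param seed integer seed.
#' @return list of records `(cluster, n_samples, result)`.
#' @export
per_cluster_analysis <- function(expr, surv, partition, b = 1000L,
                                 set_size = 64L, min_cluster_size = 10L,
                                 seed = 1L) {
  stopifnot(inherits(partition, "ClusterPartition"))
  ac <- align_cohort(expr, surv)
  idx <- match(ac$expr$sample_ids, partition$sample_ids)
  if (anyNA(idx))
    stop("partition does not cover all samples", call. = FALSE)
  labels <- partition$labels[idx]
  groups <- split(seq_along(labels), labels)
  run_group_analyses(ac, groups, names(groups), b, set_size,
                     min_cluster_size, seed, what = "cluster")
}

#' Bias analysis on size-matched random subsamples
#'
#' The control arm for the per-cluster analysis: for each requested
#' size, a uniformly random sample subset of that size is analyzed
#' exactly as a cluster would be, including its own recomputed null.
#'
#' @param expr,surv the full cohort.
#' @param cluster_sizes integer vector of subset sizes.
#' @param b,set_size as in [per_cluster_analysis()].
#' @param seed integer seed.
#' @return list of records `(replicate, n_samples, result)`.
#' @export
subsample_control <- function(expr, surv, cluster_sizes, b = 1000L,
                              set_size = 64L, seed = 1L) {
  if (!length(cluster_sizes)) stop("empty size list", call. = FALSE)
  ac <- align_cohort(expr, surv)
  n <- length(ac$expr$sample_ids)
  if (any(cluster_sizes > n))
    stop("subsample size exceeds cohort size", call. = FALSE)
  groups <- with_seed(derive_seed(seed, 23L),
                      lapply(cluster_sizes,
                             function(sz) sample.int(n, sz)))
  run_group_analyses(ac, groups, seq_along(groups), b, set_size,
                     min_size = 1L, seed = seed, what = "replicate")
}

#' Bias analysis stratified by a clinical label
#'
#' Same machinery as [per_cluster_analysis()] but with groups defined by
#' a clinical label (e.g. grade). Samples with missing labels are
#' excluded with a message; groups below `min_group_size` are skipped.
#'
#' @param expr,surv the full cohort.
#' @param labels a [clinical_labels()].
#' @param b,set_size as in [per_cluster_analysis()].
#' @param min_group_size smallest group analyzed (default 10).
#' @param seed integer seed.
#' @return list of records `(label, n_samples, result)`.
#' @export
stratify_by_label <- function(expr, surv, labels, b = 1000L,
                              set_size = 64L, min_group_size = 10L,
                              seed = 1L) {
  stopifnot(inherits(labels, "ClinicalLabels"))
  ac <- align_cohort(expr, surv)
  lab <- labels$label[match(ac$expr$sample_ids, labels$sample_ids)]
  miss <- is.na(lab)
  if (any(miss))
    message(sprintf("%d sample(s) without a label excluded", sum(miss)))
  groups <- split(which(!miss), lab[!miss])
  run_group_analyses(ac, groups, names(groups), b, set_size,
                     min_group_size, seed, what = "label")
}

# shared engine for per-cluster / subsample / per-label restricted runs
run_group_analyses <- function(ac, groups, ids, b, set_size, min_size,
                               seed, what) {
  out <- list()
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    if (length(members) < min_size) {
      warning(sprintf("%s '%s' has %d < %d samples; skipped", what,
                      ids[gi], length(members), min_size),
              call. = FALSE)
      next
    }
    sub <- subset_cohort(ac$expr, ac$surv, members)
    if (sum(sub$surv$event) < 1L) {
      warning(sprintf("%s '%s' has no events; skipped", what, ids[gi]),
              call. = FALSE)
      next
    }
    R <- null_pvalues(sub$surv, b, seed = derive_seed(seed, 1000L + gi))
    P <- random_set_pvalues(sub$expr, sub$surv, set_size, b,
                            seed = derive_seed(seed, 2000L + gi))
    rec <- list(id = ids[gi], n_samples = length(members),
                result = bias_result(P, R))
    names(rec)[1L] <- what
    out[[length(out) + 1L]] <- rec
  }
  if (!length(out))
    stop(sprintf("no %s meets the minimum size", what), call. = FALSE)
  out
}

#' Render a dataset report to disk
#'
#' Writes flat numeric tables shaped like the standard summaries:
#' `table1.tsv` (Signif %, P-value and, when adjusted, PCNA %,
#' PCNA p-val, at the reporting set size), `table2.tsv` when the
#' consistency analysis was run, `clusters.tsv` with the per-cluster and
#' subsample-control proportions next to the pooled one, and
#' `diagnostics.tsv` with the p-value histogram of the reporting size
#' against its null.
#'
#' @param report a `DatasetReport`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "DatasetReport"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  size <- report$provenance$set_size
  pick <- function(profile) {
    i <- match(size, profile$set_sizes)
    profile$results[[if (is.na(i)) length(profile$results) else i]]
  }
  raw <- pick(report$bias_raw)
  t1 <- data.frame(dataset = report$dataset_label,
                   signif_pct = 100 * raw$prop_signif,
                   p_value = raw$p_two_sided)
  if (!is.null(report$bias_adjusted)) {
    adj <- pick(report$bias_adjusted)
    t1$pcna_pct <- 100 * adj$prop_signif
    t1$pcna_pval <- adj$p_two_sided
  }
  p1 <- file.path(out_dir, "table1.tsv")
  data.table::fwrite(t1, p1, sep = "\t")
  paths <- c(paths, p1)

  if (!is.null(report$consistency)) {
    cs <- report$consistency
    t2 <- data.frame(dataset = report$dataset_label,
                     samples = report$n_samples,
                     signif_pct = 100 * cs$per_half_signif_prop,
                     repeat_pct = 100 * cs$repeat_prop,
                     p_value = cs$fisher_p, odds_ratio = cs$odds_ratio)
    p2 <- file.path(out_dir, "table2.tsv")
    data.table::fwrite(t2, p2, sep = "\t")
    paths <- c(paths, p2)
  }

  if (length(report$per_cluster) || length(report$subsample_control)) {
    rows <- list()
    add <- function(recs, src) {
      for (r in recs) {
        rows[[length(rows) + 1L]] <<- data.frame(
          source = src, id = as.character(r[[1L]]),
          n_samples = r$n_samples,
          prop_signif = r$result$prop_signif,
          p_two_sided = r$result$p_two_sided,
          direction = r$result$direction,
          pooled_prop_signif = raw$prop_signif)
      }
    }
    add(report$per_cluster, "cluster")
    add(report$subsample_control, "subsample")
    p3 <- file.path(out_dir, "clusters.tsv")
    data.table::fwrite(do.call(rbind, rows), p3, sep = "\t")
    paths <- c(paths, p3)
  }

  i <- match(size, report$bias_raw$set_sizes)
  if (is.na(i)) i <- length(report$bias_raw$pvalues)
  diag <- pvalue_diagnostics(report$bias_raw$pvalues[[i]],
                             report$bias_raw$null)
  p4 <- file.path(out_dir, "diagnostics.tsv")
  data.table::fwrite(diag$histogram, p4, sep = "\t")
  paths <- c(paths, p4)
  invisible(paths)
}
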