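# Half-split consistency: are random gene sets that predict survival in
# one random half of the cohort significant again in the other half more
# often than chance?

#' Bernoulli half split of a cohort
#'
#' Each sample is assigned to one of two halves by an independent fair
#' coin; an empty half triggers a redraw (counted in the `n_redrawn`
#' attribute).
#'
#' @param sample_ids character vector, length >= 8.
#' @param seed integer seed.
#' @return list with `half_a` and `half_b` (disjoint sample-id vectors)
#'   and attribute `n_redrawn`.
#' @export
bernoulli_half_split <- function(sample_ids, seed = NULL) {
  n <- length(sample_ids)
  if (n < 8L) stop("need >= 8 samples", call. = FALSE)
  with_seed(seed, {
    n_redrawn <- 0L
    repeat {
      in_a <- stats::runif(n) < 0.5
      if (any(in_a) && !all(in_a)) break
      n_redrawn <- n_redrawn + 1L
    }
    out <- list(half_a = sample_ids[in_a], half_b = sample_ids[!in_a])
    attr(out, "n_redrawn") <- n_redrawn
    out
  })
}

#' Half-split consistency analysis
#'
#' Repeatedly splits the cohort into two random halves (fair coin per
#' sample); within each split, draws random gene sets and evaluates the
#' PC1 / median-split / log-rank p-value separately in each half. A set
#' is significant in a half if its raw log-rank p falls below `alpha`.
#' All `n_splits * sets_per_split` sets are pooled into one 2x2 table
#' (significant-in-A by significant-in-B), tested for enrichment of
#' double-significant sets with a one-sided Fisher exact test. Splits
#' where a half is too small to analyze or has no events are redrawn and
#' counted.
#'
#' @param expr an [expression_matrix()].
#' @param surv a [survival_table()].
#' @param set_size genes per random set (default 64).
#' @param n_splits number of half-splits (default 50).
#' @param sets_per_split random sets per split (default 100).
#' @param alpha per-half significance threshold on the raw log-rank p.
#' @param seed integer seed.
#' @return list of class `ConsistencyResult` with the pooled table, the
#'   mean per-half significant proportion, the both-halves proportion,
#'   the sample odds ratio, and the one-sided Fisher p.
#' @export
consistency_analysis <- function(expr, surv, set_size = 64L,
                                 n_splits = 50L, sets_per_split = 100L,
                                 alpha = 0.05, seed = 1L) {
  if (!is_count(n_splits)) stop("n_splits must be a positive integer",
                                call. = FALSE)
  if (!is_count(sets_per_split))
    stop("sets_per_split must be a positive integer", call. = FALSE)
  ac <- align_cohort(expr, surv)
  values <- ac$expr$values
  m <- nrow(values)
  if (!is_count(set_size) || set_size > m)
    stop("set_size must be an integer in [1, n_genes]", call. = FALSE)
  n <- length(ac$surv$sample_ids)
  if (n < 8L) stop("need >= 8 samples", call. = FALSE)
  time <- ac$surv$time; event <- ac$surv$event
  with_seed(seed, {
    sig_a <- logical(0); sig_b <- logical(0)
    n_redrawn <- 0L
    for (split in seq_len(n_splits)) {
      repeat {
        in_a <- stats::runif(n) < 0.5
        ok <- function(mask) sum(mask) >= 4L && sum(event[mask]) >= 1L
        if (ok(in_a) && ok(!in_a)) break
        n_redrawn <- n_redrawn + 1L
      }
      prep_a <- logrank_prep(time[in_a], event[in_a])
      prep_b <- logrank_prep(time[!in_a], event[!in_a])
      va <- values[, in_a, drop = FALSE]
      vb <- values[, !in_a, drop = FALSE]
      for (j in seq_len(sets_per_split)) {
        idx <- sample.int(m, set_size)
        pa <- half_pvalue(va[idx, , drop = FALSE], prep_a)
        pb <- half_pvalue(vb[idx, , drop = FALSE], prep_b)
        sig_a <- c(sig_a, pa < alpha)
        sig_b <- c(sig_b, pb < alpha)
      }
    }
    if (n_redrawn > 0L)
      message(sprintf("%d half-split(s) redrawn", n_redrawn))
    a <- sum(sig_a & sig_b); b_ <- sum(sig_a & !sig_b)
    c_ <- sum(!sig_a & sig_b); d <- sum(!sig_a & !sig_b)
    fe <- fisher_exact(a, b_, c_, d, side = "greater")
    total <- a + b_ + c_ + d
    structure(list(
      n_splits = n_splits, sets_per_split = sets_per_split,
      set_size = as.integer(set_size), alpha = alpha,
      table = c(both = a, a_only = b_, b_only = c_, neither = d),
      per_half_signif_prop = (sum(sig_a) + sum(sig_b)) / (2 * total),
      repeat_prop = a / total,
      odds_ratio = fe$odds_ratio, fisher_p = fe$p_value,
      n_redrawn = n_redrawn, seed = as.integer(seed)),
      class = "ConsistencyResult")
  })
}

# p-value for one half: PC1 -> median split -> log-rank; degenerate
# halves contribute p = 1 (no separation evidence)
half_pvalue <- function(x, prep) {
  v <- pc1_scores_fast(x)
  if (is.null(v)) return(1)
  grp <- median_split_fast(as.vector(v))
  if (is.null(grp)) return(1)
  logrank_p_fast(prep, grp)
}

#' @export
print.ConsistencyResult <- function(x, ...) {
  cat(sprintf(
    "ConsistencyResult: size %d, %d splits x %d sets | signif %.1f%%/half, repeat %.1f%% | OR = %.2f, Fisher p = %.3g\n",
    x$set_size, x$n_splits, x$sets_per_split,
    100 * x$per_half_signif_prop, 100 * x$repeat_prop, x$odds_ratio,
    x$fisher_p))
  invisible(x)
}

#' @export
as.data.frame.ConsistencyResult <- function(x, ...) {
  data.frame(set_size = x$set_size, n_splits = x$n_splits,
             sets_per_split = x$sets_per_split,
             per_half_signif_prop = x$per_half_signif_prop,
             repeat_prop = x$repeat_prop, odds_ratio = x$odds_ratio,
             fisher_p = x$fisher_p)
}
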