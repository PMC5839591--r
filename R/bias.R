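# The core resampling procedure: score samples by PC1 of a random gene
# subset, median-split, log-rank; repeat b times; compare the proportion
# of significant sets against an empirical null of random equal-sized
# group assignments; test that proportion with a two-proportion Z.

# ---- internal log-rank fast path -------------------------------------
# Everything that depends only on (time, event) is computed once per
# dataset; each of the b draws then costs two cumsum/rowsum passes.

logrank_prep <- function(time, event) {
  ord <- order(time)
  d_s <- event[ord]
  t_s <- time[ord]
  uniq <- !duplicated(t_s)
  grp <- cumsum(uniq)
  n <- length(t_s)
  n_at <- (n:1)[uniq]
  d_tot <- as.vector(rowsum(d_s, grp))
  keep <- d_tot > 0
  list(ord = ord, d_s = d_s, uniq = uniq, grp = grp, n_at = n_at,
       d_tot = d_tot, keep = keep, n_events = sum(event))
}

logrank_stat_fast <- function(prep, in1) {
  g1 <- as.integer(in1[prep$ord])
  n1_at <- rev(cumsum(rev(g1)))[prep$uniq]
  d1 <- as.vector(rowsum(prep$d_s * g1, prep$grp))
  k <- prep$keep
  nj <- prep$n_at[k]; dj <- prep$d_tot[k]
  n1j <- n1_at[k]; d1j <- d1[k]
  oe <- sum(d1j - dj * n1j / nj)
  vj <- dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / pmax(nj - 1, 1)
  vj[nj <= 1] <- 0
  v <- sum(vj)
  if (v > 0) oe^2 / v else 0
}

logrank_p_fast <- function(prep, in1) {
  stats::pchisq(logrank_stat_fast(prep, in1), df = 1, lower.tail = FALSE)
}

# ---- building blocks --------------------------------------------------

#' Sample a random gene set
#'
#' `set_size` distinct gene indices, uniform over all subsets of that
#' size.
#'
#' @param n_genes number of genes available.
#' @param set_size subset size.
#' @param seed optional integer seed.
#' @return integer vector of gene indices.
#' @export
sample_gene_set <- function(n_genes, set_size, seed = NULL) {
  if (!is_count(set_size) || set_size > n_genes)
    stop("set_size must be an integer in [1, n_genes]", call. = FALSE)
  with_seed(seed, sample.int(n_genes, set_size))
}

#' First principal component sample scores
#'
#' Centers each gene row and projects samples onto the first right
#' singular vector of the centered submatrix. The returned vector has
#' unit norm; its sign is unconstrained (the downstream median split is
#' sign-invariant). Zero-variance gene rows are dropped with a warning.
#'
#' @param submatrix an [expression_matrix()] restricted to a gene set, or
#'   a plain genes x samples numeric matrix.
#' @return numeric vector of per-sample scores.
#' @export
pc1_scores <- function(submatrix) {
  x <- if (inherits(submatrix, "ExpressionMatrix")) submatrix$values
       else as.matrix(submatrix)
  if (ncol(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  v <- pc1_scores_fast(x)
  if (is.null(v))
    stop("all genes have zero variance", call. = FALSE)
  if (attr(v, "n_dropped") > 0L)
    warning(sprintf("%d zero-variance gene(s) dropped before SVD",
                    attr(v, "n_dropped")), call. = FALSE)
  as.vector(v)
}

# NULL when every row is constant; otherwise unit-norm score vector with
# attribute n_dropped. Works on the smaller Gram side for speed.
pc1_scores_fast <- function(x) {
  xc <- x - rowMeans(x)
  keep <- rowSums(xc * xc) > 0
  n_dropped <- sum(!keep)
  if (!any(keep)) return(NULL)
  xc <- xc[keep, , drop = FALSE]
  s <- nrow(xc); n <- ncol(xc)
  if (s == 1L) {
    v <- xc[1L, ]
  } else if (s <= n) {
    g <- tcrossprod(xc)
    u <- eigen(g, symmetric = TRUE)$vectors[, 1L]
    v <- as.vector(crossprod(xc, u))
  } else {
    g <- crossprod(xc)
    v <- eigen(g, symmetric = TRUE)$vectors[, 1L]
  }
  v <- v / sqrt(sum(v^2))
  attr(v, "n_dropped") <- n_dropped
  v
}

#' Median split of sample scores
#'
#' Samples strictly below the median form the low group, strictly above
#' the high group; samples exactly at the median are assigned in stable
#' input order to the low group until it reaches ceiling(n/2), then to
#' the high group, so the split is deterministic and the group sizes are
#' ceiling(n/2) and floor(n/2).
#'
#' @param scores numeric vector, length >= 4.
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  n <- length(scores)
  if (n < 4L) stop("need >= 4 samples", call. = FALSE)
  lab <- median_split_fast(scores)
  if (is.null(lab)) stop("degenerate scores: all identical", call. = FALSE)
  factor(ifelse(lab, "high", "low"), levels = c("low", "high"))
}

# logical vector (TRUE = high group) or NULL when degenerate
median_split_fast <- function(scores) {
  med <- stats::median(scores)
  lo <- scores < med
  hi <- scores > med
  if (!any(lo) && !any(hi)) return(NULL)
  n_lo_target <- ceiling(length(scores) / 2)
  at <- which(!lo & !hi)
  room <- n_lo_target - sum(lo)
  if (length(at)) {
    take <- at[seq_len(min(room, length(at)))]
    lo[take] <- TRUE
  }
  !lo
}

# ---- p-value samples --------------------------------------------------

new_pvalue_sample <- function(p_values, set_size, b, seed, source,
                              n_redrawn = 0L) {
  structure(list(p_values = p_values, set_size = set_size, b = b,
                 seed = seed, source = source, n_redrawn = n_redrawn),
            class = "PValueSample")
}

#' @export
as.data.frame.PValueSample <- function(x, ...) {
  data.frame(draw = seq_len(x$b), p_value = x$p_values,
             set_size = x$set_size, source = x$source)
}

#' Log-rank p-values of random gene sets
#'
#' Draws `b` random gene sets of a fixed size; for each, computes PC1
#' sample scores, median-splits, and runs the log-rank test. A fully
#' degenerate draw (every sampled gene constant, or all scores tied) is
#' redrawn and counted so that exactly `b` valid p-values are returned.
#'
#' @param expr an [expression_matrix()].
#' @param surv a [survival_table()] (aligned via [align_cohort()]).
#' @param set_size genes per random set.
#' @param b number of random sets.
#' @param seed integer seed.
#' @return a `PValueSample` with `source = "random_gene_sets"`.
#' @export
random_set_pvalues <- function(expr, surv, set_size, b, seed = 1L) {
  ac <- align_cohort(expr, surv)
  if (!is_count(b)) stop("b must be a positive integer", call. = FALSE)
  if (!is_count(set_size) || set_size > nrow(ac$expr$values))
    stop("set_size must be an integer in [1, n_genes]", call. = FALSE)
  if (sum(ac$surv$event) < 1L) stop("no events", call. = FALSE)
  values <- ac$expr$values
  m <- nrow(values)
  prep <- logrank_prep(ac$surv$time, ac$surv$event)
  with_seed(seed, {
    p <- numeric(b)
    n_redrawn <- 0L
    for (i in seq_len(b)) {
      repeat {
        idx <- sample.int(m, set_size)
        v <- pc1_scores_fast(values[idx, , drop = FALSE])
        if (!is.null(v)) {
          grp <- median_split_fast(as.vector(v))
          if (!is.null(grp)) break
        }
        n_redrawn <- n_redrawn + 1L
      }
      p[i] <- logrank_p_fast(prep, grp)
    }
    if (n_redrawn > 0L)
      message(sprintf("%d degenerate draw(s) redrawn", n_redrawn))
    new_pvalue_sample(p, set_size, b, seed, "random_gene_sets", n_redrawn)
  })
}

#' Log-rank p-values of random equal-sized group assignments
#'
#' The empirical null: `b` uniformly random partitions of the samples
#' into groups of sizes ceiling(n/2) and floor(n/2) — mirroring the
#' median-split group sizes — each scored by the log-rank test. Depends
#' only on the survival data, so one null sample serves every set size.
#'
#' @param surv a [survival_table()].
#' @param b number of random assignments.
#' @param seed integer seed.
#' @return a `PValueSample` with `source = "null_assignments"`.
#' @export
null_pvalues <- function(surv, b, seed = 1L) {
  stopifnot(inherits(surv, "SurvivalTable"))
  if (!is_count(b)) stop("b must be a positive integer", call. = FALSE)
  if (sum(surv$event) < 1L) stop("no events", call. = FALSE)
  n <- length(surv$time)
  n1 <- ceiling(n / 2)
  prep <- logrank_prep(surv$time, surv$event)
  with_seed(seed, {
    p <- numeric(b)
    for (i in seq_len(b)) {
      in1 <- logical(n)
      in1[sample.int(n, n1)] <- TRUE
      p[i] <- logrank_p_fast(prep, in1)
    }
    new_pvalue_sample(p, NA_integer_, b, seed, "null_assignments")
  })
}

# ---- the bias statistic ----------------------------------------------

#' Proportion of significant random sets
#'
#' Threshold at the 5th percentile of the null p-values (linear
#' interpolation rule) and count the strictly smaller gene-set p-values.
#'
#' @param P `PValueSample` from [random_set_pvalues()].
#' @param R `PValueSample` from [null_pvalues()].
#' @return list with `threshold_r` and `prop_signif`.
#' @export
significant_proportion <- function(P, R) {
  stopifnot(inherits(P, "PValueSample"), inherits(R, "PValueSample"))
  threshold_r <- empirical_percentile(R$p_values, 5)
  list(threshold_r = threshold_r,
       prop_signif = mean(P$p_values < threshold_r))
}

#' Two-proportion Z test for the significant proportion
#'
#' Central-limit statistic for the difference between the observed
#' proportion of significant random sets and the nominal 0.05, with the
#' number of random draws b as the CLT sample size on both sides:
#' z = (p - 0.05) / sqrt(p(1-p)/b + 0.05 * 0.95 / b).
#'
#' @param prop_signif observed proportion in `[0, 1]`.
#' @param b number of random draws behind the proportion.
#' @return list with `z` and `p_two_sided`.
#' @export
proportion_z_test <- function(prop_signif, b) {
  if (!is_count(b, min = 2L)) stop("b must be an integer >= 2",
                                   call. = FALSE)
  if (!is_prob(prop_signif))
    stop("prop_signif must be in [0, 1]", call. = FALSE)
  se <- sqrt(prop_signif * (1 - prop_signif) / b + 0.05 * 0.95 / b)
  z <- (prop_signif - 0.05) / se
  list(z = z, p_two_sided = 2 * stats::pnorm(-abs(z)))
}

new_bias_result <- function(set_size, b, threshold_r, prop_signif,
                            alpha = 0.05) {
  zt <- proportion_z_test(prop_signif, b)
  direction <- if (zt$p_two_sided < alpha && prop_signif > 0.05) "positive"
               else if (zt$p_two_sided < alpha && prop_signif < 0.05) "negative"
               else "none"
  structure(list(set_size = set_size, b = b, threshold_r = threshold_r,
                 prop_signif = prop_signif, z = zt$z,
                 p_two_sided = zt$p_two_sided, direction = direction),
            class = "BiasResult")
}

#' Summarize one (set size, dataset) bias analysis
#'
#' Combines [significant_proportion()] and [proportion_z_test()] into a
#' single record with the bias direction call: `positive` when the
#' proportion test is significant at 0.05 and the proportion exceeds
#' 0.05, `negative` when significant and below, otherwise `none`.
#'
#' @param P,R `PValueSample`s as in [significant_proportion()].
#' @return list of class `BiasResult`.
#' @export
bias_result <- function(P, R) {
  sp <- significant_proportion(P, R)
  new_bias_result(P$set_size, P$b, sp$threshold_r, sp$prop_signif)
}

#' @export
print.BiasResult <- function(x, ...) {
  cat(sprintf(
    "BiasResult: size %d, b = %d | signif %.1f%% (null 5th pct %.4g) | Z = %.2f, p = %.3g -> %s bias\n",
    x$set_size, x$b, 100 * x$prop_signif, x$threshold_r, x$z,
    x$p_two_sided, x$direction))
  invisible(x)
}

#' @export
as.data.frame.BiasResult <- function(x, ...) {
  data.frame(set_size = x$set_size, b = x$b, threshold_r = x$threshold_r,
             prop_signif = x$prop_signif, z = x$z,
             p_two_sided = x$p_two_sided, direction = x$direction)
}

#' Full bias profile over a sweep of set sizes
#'
#' Runs the random-set analysis at each size against a single shared
#' empirical null (the null depends only on survival, not on genes).
#'
#' @param expr an [expression_matrix()].
#' @param surv a [survival_table()].
#' @param set_sizes strictly increasing integer vector; default 2^(0:10).
#' @param b random sets per size (and null assignments).
#' @param seed integer seed.
#' @param dataset_label label recorded in the profile.
#' @param adjusted logical provenance flag: was the expression
#'   proliferation-adjusted before this run?
#' @return list of class `BiasProfile` with one `BiasResult` per size.
#' @export
run_bias_analysis <- function(expr, surv, set_sizes = 2^(0:10), b = 5000L,
                              seed = 1L, dataset_label = "dataset",
                              adjusted = FALSE) {
  if (!length(set_sizes)) stop("set_sizes must be non-empty",
                               call. = FALSE)
  if (any(diff(set_sizes) <= 0))
    stop("set_sizes must be strictly increasing", call. = FALSE)
  ac <- align_cohort(expr, surv)
  R <- null_pvalues(ac$surv, b, seed = derive_seed(seed, 1L))
  results <- vector("list", length(set_sizes))
  pvalues <- vector("list", length(set_sizes))
  for (i in seq_along(set_sizes)) {
    P <- random_set_pvalues(ac$expr, ac$surv, set_sizes[i], b,
                            seed = derive_seed(seed, 100L + i))
    results[[i]] <- bias_result(P, R)
    pvalues[[i]] <- P
  }
  structure(list(results = results, dataset_label = dataset_label,
                 adjusted = adjusted, set_sizes = as.integer(set_sizes),
                 b = as.integer(b), seed = as.integer(seed),
                 threshold_r = results[[1L]]$threshold_r,
                 pvalues = pvalues, null = R),
            class = "BiasProfile")
}

#' @export
print.BiasProfile <- function(x, ...) {
  cat(sprintf("BiasProfile '%s'%s: b = %d\n", x$dataset_label,
              if (x$adjusted) " (adjusted)" else "", x$b))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.BiasProfile <- function(x, ...) {
  df <- do.call(rbind, lapply(x$results, as.data.frame))
  df$dataset_label <- x$dataset_label
  df$adjusted <- x$adjusted
  df
}

#' Diagnostics comparing gene-set and null p-value distributions
#'
#' Numeric summaries backing p-value distribution plots: a 20-bin
#' histogram of each sample on `[0, 1]`, quantile-quantile pairs of P
#' against R, and empirical CDF point sets for both.
#'
#' @param P,R `PValueSample`s.
#' @return list of class `PValueDiagnostics` with `histogram`, `qq`, and
#'   `cdf` data frames.
#' @export
pvalue_diagnostics <- function(P, R) {
  stopifnot(inherits(P, "PValueSample"), inherits(R, "PValueSample"))
  breaks <- seq(0, 1, length.out = 21L)
  hp <- graphics::hist(P$p_values, breaks = breaks, plot = FALSE)$counts
  hr <- graphics::hist(R$p_values, breaks = breaks, plot = FALSE)$counts
  nq <- min(P$b, R$b)
  probs <- stats::ppoints(nq)
  qq <- data.frame(
    null_quantile = stats::quantile(R$p_values, probs, type = 7,
                                    names = FALSE),
    observed_quantile = stats::quantile(P$p_values, probs, type = 7,
                                        names = FALSE))
  cdf <- rbind(
    data.frame(source = "random_gene_sets", p = sort(P$p_values),
               cdf = seq_len(P$b) / P$b),
    data.frame(source = "null_assignments", p = sort(R$p_values),
               cdf = seq_len(R$b) / R$b))
  structure(list(
    histogram = data.frame(bin_low = breaks[-21L], bin_high = breaks[-1L],
                           count_gene_sets = hp, count_null = hr),
    qq = qq, cdf = cdf), class = "PValueDiagnostics")
}
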