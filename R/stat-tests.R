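# Statistical primitives used throughout the pipeline.

#' Two-sample log-rank test
#'
#' Standard two-group log-rank: at each distinct event time the observed
#' minus expected number of events in group 1 is accumulated over the risk
#' set, with the hypergeometric variance and the usual correction for tied
#' event times; the statistic (sum(O-E))^2 / sum(V) is referred to
#' chi-square with 1 degree of freedom. Implemented as a vectorized
#' O(n log n) pass because the bias analysis calls it tens of thousands of
#' times per dataset.
#'
#' @param groups binary group label per sample (logical, 0/1, or a
#'   two-level factor/character vector), aligned with `surv`.
#' @param surv a [survival_table()].
#' @return list of class `LogRankResult`: `statistic` (chi-square, 1 df),
#'   `p_value`, `n_events`.
#' @export
logrank_test <- function(groups, surv) {
  stopifnot(inherits(surv, "SurvivalTable"))
  g <- as.integer(factor(groups))
  n <- length(surv$time)
  if (length(g) != n)
    stop("groups length must match survival table", call. = FALSE)
  lev <- sort(unique(g))
  if (length(lev) != 2L)
    stop("exactly two non-empty groups required", call. = FALSE)
  d_all <- surv$event
  if (sum(d_all) == 0L) stop("no events", call. = FALSE)
  in1 <- g == lev[1L]

  ord <- order(surv$time)
  t_s <- surv$time[ord]
  d_s <- d_all[ord]
  g1_s <- as.integer(in1[ord])

  # risk-set sizes just before each distinct time, via reverse cumsums
  uniq <- !duplicated(t_s)
  n_at <- rev(cumsum(rev(rep(1L, n))))[uniq]        # total at risk
  n1_at <- rev(cumsum(rev(g1_s)))[uniq]             # group-1 at risk
  grp_time <- cumsum(uniq)                          # distinct-time index
  d_tot <- as.vector(rowsum(d_s, grp_time))         # events at each time
  d1 <- as.vector(rowsum(d_s * g1_s, grp_time))     # group-1 events

  keep <- d_tot > 0
  nj <- n_at[keep]; n1j <- n1_at[keep]
  dj <- d_tot[keep]; d1j <- d1[keep]
  oe <- sum(d1j - dj * n1j / nj)
  vj <- dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / pmax(nj - 1, 1)
  vj[nj <= 1] <- 0
  v <- sum(vj)
  stat <- if (v > 0) oe^2 / v else 0
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 n_events = sum(d_all)),
            class = "LogRankResult")
}

#' Fisher exact test on a 2x2 table
#'
#' The odds ratio is the sample odds ratio a*d / (b*c) (infinite when
#' b*c = 0 and a*d > 0); p-values come from the exact hypergeometric
#' distribution with fixed margins, using the minimum-likelihood rule for
#' the two-sided case.
#'
#' @param a,b,c,d non-negative integer cell counts; row 1 = (a, b),
#'   row 2 = (c, d).
#' @param side `"two_sided"` or `"greater"` (enrichment of cell a).
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(a, b, c, d, side = c("two_sided", "greater")) {
  side <- match.arg(side)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  tab <- matrix(cells, nrow = 2L, byrow = TRUE)
  alt <- if (side == "greater") "greater" else "two.sided"
  p <- stats::fisher.test(tab, alternative = alt)$p.value
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= overlap) where X counts the intersection of two uniformly drawn
#' subsets of sizes `draws1` and `draws2` from a universe of size
#' `universe`.
#'
#' @param overlap observed intersection size.
#' @param draws1,draws2 subset sizes.
#' @param universe universe size.
#' @return probability in `[0, 1]`.
#' @export
hypergeometric_tail <- function(overlap, draws1, draws2, universe) {
  if (overlap < 0 || draws1 < 0 || draws2 < 0 ||
      max(draws1, draws2) > universe || overlap > min(draws1, draws2))
    stop("inconsistent hypergeometric arguments", call. = FALSE)
  stats::phyper(overlap - 1, draws1, universe - draws1, draws2,
                lower.tail = FALSE)
}

#' Spearman correlation distance
#'
#' 1 - rho with average ranks for ties; range `[0, 2]`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the distance.
#' @export
spearman_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("vectors must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  1 - stats::cor(x, y, method = "spearman")
}

#' Empirical percentile with linear interpolation
#'
#' The linear, inclusive order-statistic rule: rank position
#' (n - 1) * q/100 + 1, interpolating between the bracketing order
#' statistics (R's quantile type 7). Fixed package-wide so the null
#' 5th-percentile threshold is reproducible.
#'
#' @param values non-empty numeric vector.
#' @param q percentile in `[0, 100]`.
#' @return the percentile value.
#' @export
empirical_percentile <- function(values, q) {
  if (!length(values)) stop("empty vector", call. = FALSE)
  if (q < 0 || q > 100) stop("q must be in [0, 100]", call. = FALSE)
  unname(stats::quantile(values, probs = q / 100, type = 7, names = FALSE))
}
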