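# The core resampling machinery: gene-set sampling, PC1 scoring, median
# split, p-value samples, and the proportion statistic.

test_that("sample_gene_set is uniform, distinct and deterministic", {
  expect_setequal(sample_gene_set(5, 5, seed = 1), 1:5)
  a <- sample_gene_set(10, 3, seed = 2)
  expect_length(unique(a), 3)
  expect_identical(a, sample_gene_set(10, 3, seed = 2))
  expect_error(sample_gene_set(5, 6), "set_size")
  # frequency: 50000 singleton draws, each index ~5000 +- 300 (3 sigma)
  set.seed(8)
  draws <- replicate(50000, sample_gene_set(10, 1))
  expect_true(all(abs(table(draws) - 5000) <= 300))
})

test_that("pc1_scores recovers exact low-rank structure", {
  # rank-1: values[g, i] = lambda_g * v_i plus constant offsets
  v <- c(-2, 0, 1, 3)
  lam <- c(1, -0.5, 2)
  x <- outer(lam, v) + c(10, 20, 30)
  s <- pc1_scores(x)
  expect_equal(abs(cor(s, v)), 1, tolerance = 1e-9)
  expect_equal(sum(s^2), 1, tolerance = 1e-12)

  # 2x3 worked example: centered rows (-1,0,1) and (1,0,-1)
  s2 <- pc1_scores(matrix(c(1, 2, 3, 3, 2, 1), nrow = 2, byrow = TRUE))
  expect_equal(abs(s2), c(1, 0, 1) / sqrt(2), tolerance = 1e-9)
})

test_that("pc1 sign flips never change the induced median split", {
  # with an even number of samples and distinct scores (the continuous-
  # score regime of the analysis) negating the scores only swaps the
  # group labels, leaving the partition and hence the log-rank p intact
  set.seed(21)
  for (rep in 1:20) {
    s <- rnorm(2 * sample(3:15, 1))
    expect_identical(as.character(median_split(s)),
                     ifelse(median_split(-s) == "low", "high", "low"))
  }
  # odd n keeps the ceiling/floor group sizes deterministically
  sizes <- table(median_split(c(0.4, -1, 2, 0.1, 0.9)))
  expect_equal(sort(as.integer(sizes)), c(2L, 3L))
})

test_that("pc1_scores drops zero-variance genes and rejects all-constant", {
  x <- rbind(c(1, 1, 1), c(1, 2, 3))
  expect_warning(s <- pc1_scores(x), "zero-variance")
  expect_length(s, 3)
  expect_error(pc1_scores(matrix(1, 2, 3)), "zero variance")
})

test_that("median_split follows the deterministic tie rule", {
  expect_identical(as.character(median_split(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  # odd n: the middle value is the median tie, assigned to the low group
  expect_identical(as.character(median_split(c(5, 1, 2, 3, 4))),
                   c("high", "low", "low", "low", "high"))
  # ties at the median resolved by input order: exactly 2 vs 2
  sp <- median_split(c(1, 2, 2, 3))
  expect_identical(as.character(sp), c("low", "low", "high", "high"))
  expect_error(median_split(rep(3, 6)), "degenerate")
})

test_that("random-set p-values are uniform on a null cohort", {
  co <- generate_cohort(cohort_spec(n_samples = 150, n_genes = 400,
                                    structure = "null", seed = 31))
  P <- random_set_pvalues(co$expression, co$survival, 16, 200, seed = 5)
  expect_length(P$p_values, 200)
  ks <- suppressWarnings(ks.test(P$p_values, "punif"))
  expect_gt(ks$p.value, 0.01)
  # determinism
  P2 <- random_set_pvalues(co$expression, co$survival, 16, 200, seed = 5)
  expect_identical(P$p_values, P2$p_values)
  expect_error(random_set_pvalues(co$expression, co$survival, 16, 0),
               "b must be")
})

test_that("null assignments are calibrated at the nominal rate", {
  st <- ample_survival(n = 300, seed = 13)
  R <- null_pvalues(st, 2000, seed = 2)
  expect_identical(R$p_values, null_pvalues(st, 2000, seed = 2)$p_values)
  expect_lt(abs(mean(R$p_values < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("significant_proportion applies the fixed percentile rule strictly", {
  P <- new_pv <- randbias:::new_pvalue_sample
  p_self <- P(runif(400, 0, 1), 8L, 400L, 1L, "random_gene_sets")
  sp <- significant_proportion(p_self, p_self)
  expect_lte(sp$prop_signif, 0.05)

  ones <- P(rep(1, 10), 8L, 10L, 1L, "random_gene_sets")
  grid <- P(seq(0.1, 1, by = 0.1), NA_integer_, 10L, 1L,
            "null_assignments")
  expect_equal(significant_proportion(ones, grid)$prop_signif, 0)

  # frozen: R = (0.05, 0.10, ..., 0.50), threshold = 0.0725; 2 of 5 below
  Pv <- P(c(0.01, 0.02, 0.60, 0.70, 0.80), 8L, 5L, 1L,
          "random_gene_sets")
  Rv <- P(seq(0.05, 0.5, by = 0.05), NA_integer_, 10L, 1L,
          "null_assignments")
  sp2 <- significant_proportion(Pv, Rv)
  expect_equal(sp2$threshold_r, 0.0725, tolerance = 1e-12)
  expect_equal(sp2$prop_signif, 2 / 5)
})

test_that("the proportion Z statistic matches its closed form", {
  zt <- proportion_z_test(0.05, 5000)
  expect_equal(zt$z, 0)
  expect_equal(zt$p_two_sided, 1)

  zt2 <- proportion_z_test(0.80, 5000)
  expect_equal(zt2$z, 0.75 / sqrt((0.8 * 0.2 + 0.05 * 0.95) / 5000),
               tolerance = 1e-12)

  zt3 <- proportion_z_test(0.01, 5000)
  expect_lt(zt3$z, 0)
  expect_equal(zt3$z,
               -0.04 / sqrt((0.01 * 0.99 + 0.05 * 0.95) / 5000),
               tolerance = 1e-12)
})

test_that("run_bias_analysis is deterministic and validates sizes", {
  co <- generate_cohort(cohort_spec(n_samples = 80, n_genes = 200,
                                    structure = "null", seed = 3))
  a <- run_bias_analysis(co$expression, co$survival, set_sizes = c(4, 16),
                         b = 100, seed = 6)
  b <- run_bias_analysis(co$expression, co$survival, set_sizes = c(4, 16),
                         b = 100, seed = 6)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_error(run_bias_analysis(co$expression, co$survival,
                                 set_sizes = integer(0)), "non-empty")
  expect_error(run_bias_analysis(co$expression, co$survival,
                                 set_sizes = c(8, 8)), "increasing")
})

test_that("signal cohorts show bias rising with set size on average", {
  props <- sapply(1:8, function(s) {
    co <- generate_cohort(cohort_spec(
      n_samples = 120, n_genes = 400, structure = "global_signature",
      signature_fraction = 0.3, log_hazard_ratio = 1, seed = 40 + s))
    prof <- run_bias_analysis(co$expression, co$survival,
                              set_sizes = c(1, 8, 64), b = 150,
                              seed = 50 + s)
    vapply(prof$results, function(r) r$prop_signif, numeric(1))
  })
  avg <- rowMeans(props)
  expect_true(all(diff(avg) >= 0))
  expect_gt(avg[3], 0.05)
})

test_that("pvalue_diagnostics summarizes histogram, QQ and CDF", {
  P <- randbias:::new_pvalue_sample(seq(0.005, 0.995, by = 0.01), 8L,
                                    100L, 1L, "random_gene_sets")
  d <- pvalue_diagnostics(P, P)
  expect_equal(d$histogram$count_gene_sets, rep(5L, 20))
  expect_equal(d$qq$null_quantile, d$qq$observed_quantile)
  expect_equal(nrow(d$cdf), 200)
})
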