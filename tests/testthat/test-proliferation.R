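# Proliferation scoring and residualization.

test_that("proliferation score is the median over present signature genes", {
  vals <- rbind(c(1, 2), c(5, 2), c(9, 2), c(3, 2))
  em <- expression_matrix(vals, c("gA", "gB", "gC", "gD"),
                          c("s1", "s2"), log_transformed = TRUE)
  sc3 <- proliferation_score(em, gene_list(c("gA", "gB", "gC")))
  expect_equal(sc3$score, c(5, 2))
  # even count: mean of the two middle values -> (1,3,5,9) gives 4
  sc4 <- proliferation_score(em, gene_list(c("gA", "gB", "gC", "gD")))
  expect_equal(sc4$score[1], 4)
})

test_that("missing signature genes are counted and warned about", {
  em <- tiny_expr()
  sig <- gene_list(c("gA", "gB", "gX", "gY"))
  expect_warning(sc <- proliferation_score(em, sig), "2 signature")
  expect_equal(sc$n_signature_genes_used, 2L)
  expect_equal(sc$n_signature_genes_missing, 2L)
  expect_error(proliferation_score(em, gene_list(c("gX", "gY"))),
               "no signature gene")
})

test_that("anchor-derived signatures rank perfect correlates first", {
  set.seed(17)
  base <- rnorm(20)
  vals <- rbind(base, base * 2 + 1, matrix(rnorm(20 * 98), 98))
  em <- expression_matrix(vals, paste0("g", 1:100), paste0("s", 1:20),
                          log_transformed = TRUE)
  sig <- derive_signature_from_anchor(em, "g1", top_fraction = 0.02)
  expect_identical(sig$gene_ids[1], "g2")  # exact linear copy of anchor
  expect_length(sig$gene_ids, 2)           # ceiling(0.02 * 100)
  expect_error(derive_signature_from_anchor(em, "nope"), "absent")
})

test_that("anchor-derived signatures recover true signature genes", {
  co <- generate_cohort(cohort_spec(n_samples = 400, n_genes = 1000,
                                    structure = "global_signature",
                                    signature_fraction = 0.3,
                                    loading_sd = 1, seed = 23))
  sig <- derive_signature_from_anchor(co$expression,
                                      co$truth$anchor_gene, 0.01)
  truth_ids <- co$expression$gene_ids[co$truth$signal_genes]
  expect_gte(mean(sig$gene_ids %in% truth_ids), 0.8)
})

test_that("residualization matches the lm oracle on the 3-point example", {
  em <- expression_matrix(matrix(c(1, 2, 4), nrow = 1), "gA",
                          c("s1", "s2", "s3"), log_transformed = TRUE)
  sc <- structure(list(sample_ids = c("s1", "s2", "s3"),
                       score = c(0, 1, 2), n_signature_genes_used = 1L,
                       n_signature_genes_missing = 0L),
                  class = "ProliferationScore")
  adj <- adjust_expression(em, sc)
  expect_equal(adj$per_gene_slope, 1.5)
  expect_equal(adj$per_gene_intercept, 5 / 6)
  expect_equal(unname(adj$residuals$values[1, ]),
               c(1 / 6, -1 / 3, 1 / 6))
  fit <- lm(c(1, 2, 4) ~ c(0, 1, 2))
  expect_equal(unname(adj$residuals$values[1, ]),
               unname(residuals(fit)), tolerance = 1e-12)
})

test_that("exact linear genes zero out; orthogonal genes keep centering", {
  s <- c(1, 3, 4, 7, 10)
  perfect <- 2.5 * s - 4
  orth <- c(1, -1, 0, 1, -1)
  orth <- orth - sum(orth * (s - mean(s))) / sum((s - mean(s))^2) *
    (s - mean(s))  # force exact orthogonality to the centered score
  em <- expression_matrix(rbind(perfect, orth), c("gP", "gO"),
                          paste0("s", 1:5), log_transformed = TRUE)
  sc <- structure(list(sample_ids = paste0("s", 1:5), score = s,
                       n_signature_genes_used = 1L,
                       n_signature_genes_missing = 0L),
                  class = "ProliferationScore")
  adj <- adjust_expression(em, sc)
  expect_equal(unname(adj$residuals$values["gP", ]), rep(0, 5),
               tolerance = 1e-12)
  expect_equal(adj$per_gene_slope[[1]], 2.5)
  expect_equal(adj$per_gene_slope[[2]], 0, tolerance = 1e-12)
  expect_equal(unname(adj$residuals$values["gO", ]), orth - mean(orth),
               tolerance = 1e-12)
})

test_that("residuals are orthogonal to the score and adjustment is idempotent", {
  co <- generate_cohort(cohort_spec(n_samples = 60, n_genes = 150,
                                    structure = "global_signature",
                                    seed = 29))
  sig <- derive_signature_from_anchor(co$expression,
                                      co$truth$anchor_gene, 0.05)
  sc <- proliferation_score(co$expression, sig)
  adj <- adjust_expression(co$expression, sc)
  centered <- sc$score - mean(sc$score)
  dots <- as.vector(adj$residuals$values %*% centered)
  scale <- sqrt(rowSums(adj$residuals$values^2)) * sqrt(sum(centered^2))
  expect_lt(max(abs(dots) / pmax(scale, 1e-12)), 1e-8)

  again <- adjust_expression(adj$residuals, sc)
  expect_equal(again$residuals$values, adj$residuals$values,
               tolerance = 1e-8)
})
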