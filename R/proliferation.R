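# Proliferation meta-gene scoring and residualization: per-sample score =
# median expression over a signature gene list; every gene is then
# replaced by its residual from an ordinary least-squares fit on that
# score.

#' Per-sample proliferation score
#'
#' Median expression over the signature genes present in the matrix
#' (mean-of-middle-two for even counts). Missing signature genes are
#' counted and reported with a warning.
#'
#' @param expr an [expression_matrix()].
#' @param signature a [gene_list()], e.g. a PCNA meta-gene list.
#' @return list of class `ProliferationScore`: `sample_ids`, `score`,
#'   `n_signature_genes_used`, `n_signature_genes_missing`.
#' @export
proliferation_score <- function(expr, signature) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(signature, "GeneList"))
  present <- signature$gene_ids %in% expr$gene_ids
  if (!any(present))
    stop("no signature gene present in the expression matrix",
         call. = FALSE)
  n_missing <- sum(!present)
  if (n_missing > 0)
    warning(sprintf("%d signature gene(s) absent from the matrix",
                    n_missing), call. = FALSE)
  sub <- expr$values[match(signature$gene_ids[present], expr$gene_ids), ,
                     drop = FALSE]
  score <- apply(sub, 2L, stats::median)
  structure(list(sample_ids = expr$sample_ids, score = unname(score),
                 n_signature_genes_used = sum(present),
                 n_signature_genes_missing = n_missing),
            class = "ProliferationScore")
}

#' Derive a proliferation signature from an anchor gene
#'
#' In-dataset stand-in for an externally published meta-gene list: ranks
#' every gene by Pearson correlation with the anchor (e.g. PCNA) across
#' samples and returns the top fraction, anchor excluded. The returned
#' list carries `source = "anchor_derived"` metadata so downstream
#' provenance records which signature was used.
#'
#' @param expr an [expression_matrix()].
#' @param anchor_gene gene id present in `expr`.
#' @param top_fraction fraction of genes to keep, in (0, 0.5]; default
#'   0.01 (the customary "top 1%").
#' @return a [gene_list()] with attributes `anchor` and `source`.
#' @export
derive_signature_from_anchor <- function(expr, anchor_gene,
                                         top_fraction = 0.01) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!anchor_gene %in% expr$gene_ids)
    stop(sprintf("anchor gene '%s' absent from the matrix", anchor_gene),
         call. = FALSE)
  if (!is_scalar_num(top_fraction) || top_fraction <= 0 ||
      top_fraction > 0.5)
    stop("top_fraction must be in (0, 0.5]", call. = FALSE)
  anchor <- expr$values[match(anchor_gene, expr$gene_ids), ]
  if (stats::sd(anchor) == 0)
    stop("anchor gene has zero variance", call. = FALSE)
  sds <- apply(expr$values, 1L, stats::sd)
  r <- rep(-Inf, length(expr$gene_ids))
  ok <- sds > 0
  r[ok] <- suppressWarnings(
    as.vector(stats::cor(t(expr$values[ok, , drop = FALSE]), anchor)))
  r[match(anchor_gene, expr$gene_ids)] <- -Inf  # exclude anchor itself
  n_top <- ceiling(top_fraction * length(expr$gene_ids))
  top <- order(r, decreasing = TRUE)[seq_len(n_top)]
  out <- gene_list(expr$gene_ids[top])
  attr(out, "anchor") <- anchor_gene
  attr(out, "source") <- "anchor_derived"
  out
}

#' Residualize expression against a proliferation score
#'
#' Per gene, ordinary least squares of expression on the score (with
#' intercept); the gene's values are replaced by the residuals. Done in
#' closed form across all genes at once. Residuals are orthogonal to the
#' centered score by construction.
#'
#' @param expr an [expression_matrix()].
#' @param score a [proliferation_score()] aligned with `expr` (same
#'   sample ids, any order).
#' @return list of class `AdjustedExpression`: `residuals` (an
#'   [expression_matrix()] on the same genes/samples),
#'   `per_gene_intercept`, `per_gene_slope`.
#' @export
adjust_expression <- function(expr, score) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(score, "ProliferationScore"))
  idx <- match(expr$sample_ids, score$sample_ids)
  if (anyNA(idx))
    stop("score is missing samples present in the expression matrix",
         call. = FALSE)
  s <- score$score[idx]
  sc <- s - mean(s)
  ss <- sum(sc^2)
  if (ss == 0) stop("constant proliferation score", call. = FALSE)
  x <- expr$values
  gmean <- unname(rowMeans(x))
  slope <- as.vector((x %*% sc) / ss)
  intercept <- gmean - slope * mean(s)
  fitted <- outer(slope, s) + intercept
  res <- x - fitted
  structure(list(
    residuals = expression_matrix(res, expr$gene_ids, expr$sample_ids,
                                  log_transformed = TRUE),
    per_gene_intercept = intercept, per_gene_slope = slope),
    class = "AdjustedExpression")
}
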