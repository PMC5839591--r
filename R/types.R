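# Domain containers. All are plain S3 lists with validators, in the spirit
# of survival::Surv and phyloseq components: cheap to construct, validated
# once at the boundary, then trusted internally.

#' Construct an expression matrix container
#'
#' Genes in rows, samples in columns (the TCGA level-3 convention).
#'
#' @param values numeric matrix, genes x samples, no missing entries.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   column.
#' @param log_transformed logical; `TRUE` when values are on a log-like
#'   scale (may be negative), `FALSE` for raw non-negative abundances.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids, sample_ids,
                              log_transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids))
    stop_field("gene_ids", "length must equal nrow(values)")
  if (ncol(values) != length(sample_ids))
    stop_field("sample_ids", "length must equal ncol(values)")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop_field("gene_ids", paste0("duplicate gene ids: ",
                                  paste(dup, collapse = ", ")))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop_field("sample_ids", paste0("duplicate sample ids: ",
                                    paste(dup, collapse = ", ")))
  bad <- !stats::complete.cases(values)
  if (any(bad))
    stop_field("values", paste0("missing entries in gene(s): ",
                                paste(gene_ids[bad], collapse = ", ")))
  if (!log_transformed && any(values < 0))
    stop_field("values", "negative entries but log_transformed is FALSE")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids,
                 log_transformed = isTRUE(log_transformed)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              length(x$gene_ids), length(x$sample_ids),
              if (x$log_transformed) "log" else "raw"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Construct a survival table
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param time numeric follow-up times, finite and non-negative, one time
#'   unit throughout (e.g. days).
#' @param event 0/1 event indicators (1 = event observed, 0 = censored).
#' @return an object of class `SurvivalTable`.
#' @export
survival_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  time <- as.double(time)
  event <- as.double(event)
  n <- length(sample_ids)
  if (length(time) != n || length(event) != n)
    stop_field("time/event", "lengths must match sample_ids")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop_field("sample_ids", paste0("duplicate sample ids: ",
                                    paste(dup, collapse = ", ")))
  if (any(!is.finite(time)) || any(time < 0))
    stop_field("time", "must be finite and non-negative")
  if (!all(event %in% c(0, 1)))
    stop_field("event", "must be 0 (censored) or 1 (event)")
  structure(list(sample_ids = sample_ids, time = time,
                 event = as.integer(event)),
            class = "SurvivalTable")
}

#' @export
print.SurvivalTable <- function(x, ...) {
  cat(sprintf("SurvivalTable: %d samples, %d events (%.1f%%)\n",
              length(x$sample_ids), sum(x$event),
              100 * mean(x$event)))
  invisible(x)
}

#' Construct a gene list
#'
#' Duplicates are removed with a warning; order of first appearance is kept.
#'
#' @param gene_ids character vector of gene symbols.
#' @return an object of class `GeneList`.
#' @export
gene_list <- function(gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) stop_field("gene_ids", "must be non-empty")
  n_dup <- sum(duplicated(gene_ids))
  if (n_dup > 0) {
    warning(sprintf("%d duplicate gene symbol(s) removed", n_dup),
            call. = FALSE)
    gene_ids <- unique(gene_ids)
  }
  structure(list(gene_ids = gene_ids), class = "GeneList")
}

#' Construct a clinical label table
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param label character vector of categorical labels; `NA` encodes a
#'   missing label explicitly.
#' @return an object of class `ClinicalLabels`.
#' @export
clinical_labels <- function(sample_ids, label) {
  sample_ids <- as.character(sample_ids)
  label <- as.character(label)
  if (length(label) != length(sample_ids))
    stop_field("label", "length must match sample_ids")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop_field("sample_ids", paste0("duplicate sample ids: ",
                                    paste(dup, collapse = ", ")))
  structure(list(sample_ids = sample_ids, label = label),
            class = "ClinicalLabels")
}

#' Align an expression matrix with a survival table
#'
#' Restricts both objects to their common samples, in the expression
#' matrix's column order. A warning reports samples dropped from either
#' side; identical id sets pass through silently.
#'
#' @param expr an [expression_matrix()].
#' @param surv a [survival_table()].
#' @return list with elements `expr` and `surv`, sample-aligned.
#' @export
align_cohort <- function(expr, surv) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(surv, "SurvivalTable"))
  common <- intersect(expr$sample_ids, surv$sample_ids)
  if (!length(common))
    stop("expression and survival share no sample ids", call. = FALSE)
  n_drop <- (length(expr$sample_ids) - length(common)) +
    (length(surv$sample_ids) - length(common))
  if (n_drop > 0)
    warning(sprintf(
      "sample ids differ between expression and survival; %d sample record(s) dropped, %d retained",
      n_drop, length(common)), call. = FALSE)
  keep <- expr$sample_ids %in% common
  expr2 <- expression_matrix(expr$values[, keep, drop = FALSE],
                             expr$gene_ids, expr$sample_ids[keep],
                             expr$log_transformed)
  idx <- match(expr2$sample_ids, surv$sample_ids)
  surv2 <- survival_table(surv$sample_ids[idx], surv$time[idx],
                          surv$event[idx])
  list(expr = expr2, surv = surv2)
}

# Restrict a cohort to a subset of samples given by ids or logical/integer
# index over the expression columns.
subset_cohort <- function(expr, surv, samples) {
  if (is.character(samples)) samples <- match(samples, expr$sample_ids)
  expr2 <- expression_matrix(expr$values[, samples, drop = FALSE],
                             expr$gene_ids, expr$sample_ids[samples],
                             expr$log_transformed)
  idx <- match(expr2$sample_ids, surv$sample_ids)
  surv2 <- survival_table(surv$sample_ids[idx], surv$time[idx],
                          surv$event[idx])
  list(expr = expr2, surv = surv2)
}
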