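# File input/output. Everything downstream operates on the in-memory
# containers from types.R; this is the only module that touches disk.

#' Read a gene-expression matrix from a TSV file
#'
#' Expects the TCGA level-3 layout: tab-separated, first column gene ids,
#' header row of sample ids, numeric body. Values are optionally
#' log2(x + 1)-transformed on load (the default, appropriate for
#' RSEM-scale normalized abundances feeding correlation and PCA).
#'
#' @param path path to the TSV file.
#' @param log_transform logical; when `TRUE` (default) each value x is
#'   replaced by log2(x + 1) and the result is flagged `log_transformed`.
#'   When `FALSE`, values are returned verbatim; a file containing
#'   negative values is taken to be on a log-like scale already and
#'   flagged accordingly.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, log_transform = TRUE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2L)
    stop("expression file needs a gene-id column plus >= 1 sample column",
         call. = FALSE)
  gene_ids <- as.character(dt[[1L]])
  body <- dt[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop(sprintf("non-numeric value at row %d, column '%s'",
                   if (length(bad)) bad[1L] else NA_integer_,
                   names(body)[j]), call. = FALSE)
    }
  }
  values <- as.matrix(body)
  flag <- log_transform
  if (log_transform) {
    if (any(values < 0, na.rm = TRUE))
      stop("negative expression values: log2(x+1) transform undefined",
           call. = FALSE)
    values <- log2(values + 1)
  } else if (any(values < 0, na.rm = TRUE)) {
    # negative entries mean the file is already on a log-like scale
    flag <- TRUE
  }
  expression_matrix(values, gene_ids, colnames(body),
                    log_transformed = flag)
}

#' Write an expression matrix to a TSV file
#'
#' Inverse layout of [read_expression()]: first column `gene_id`, then one
#' column per sample. Values are written as-is (no transform is undone).
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  dt <- data.table::data.table(gene_id = expr$gene_ids)
  dt <- cbind(dt, data.table::as.data.table(expr$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a survival table from a TSV file
#'
#' Expects header columns `sample_id`, `time`, `event` (0 = censored,
#' 1 = event).
#'
#' @param path path to the TSV file.
#' @return a [survival_table()].
#' @export
read_survival <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(dt)))
    stop("survival file must have columns sample_id, time, event",
         call. = FALSE)
  survival_table(dt$sample_id, dt$time, dt$event)
}

#' Write a survival table to a TSV file
#'
#' @param surv a [survival_table()].
#' @param path output path.
#' @export
write_survival <- function(surv, path) {
  stopifnot(inherits(surv, "SurvivalTable"))
  data.table::fwrite(
    data.table::data.table(sample_id = surv$sample_ids, time = surv$time,
                           event = surv$event),
    path, sep = "\t")
  invisible(path)
}

#' Read a gene list from a plain-text file
#'
#' One symbol per line; blank lines ignored; surrounding whitespace
#' trimmed; duplicates removed with a warning.
#'
#' @param path path to the file.
#' @return a [gene_list()].
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("gene list file is empty", call. = FALSE)
  gene_list(lines)
}

#' Read clinical labels from a TSV file
#'
#' Expects header columns `sample_id` and `label`; empty labels become NA.
#'
#' @param path path to the TSV file.
#' @return a [clinical_labels()].
#' @export
read_clinical_labels <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, na.strings = c("", "NA"))
  if (!all(c("sample_id", "label") %in% names(dt)))
    stop("label file must have columns sample_id, label", call. = FALSE)
  clinical_labels(dt$sample_id, dt$label)
}

#' Write an analysis result to disk
#'
#' JSON (nested, lossless; reread with [read_results()]) or TSV (flat
#' table via the result's `as.data.frame` method). The format defaults to
#' the file extension.
#'
#' @param result a result record (`BiasResult`, `BiasProfile`,
#'   `PValueSample`, `ConsistencyResult`, `ClusterPartition`, ...).
#' @param path output path.
#' @param format `"json"` or `"tsv"`; default inferred from `path`.
#' @export
write_results <- function(result, path,
                          format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  }
  if (format == "json") {
    payload <- list(class = class(result)[1L], data = unclass_deep(result))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    df <- as.data.frame(result)
    data.table::fwrite(df, path, sep = "\t")
  }
  invisible(path)
}

#' Read back a JSON result written by [write_results()]
#'
#' @param path path to the JSON file.
#' @return the reconstructed result record with its original class.
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  out <- relist_result(payload$data)
  class(out) <- payload$class
  out
}

# strip classes recursively so jsonlite serializes plainly, recording
# them in markers so read_results() can rebuild the original records
unclass_deep <- function(x) {
  if (is.matrix(x)) {
    return(list(.matrix = TRUE, dim = dim(x), dimnames = dimnames(x),
                data = as.vector(x)))
  }
  if (is.data.frame(x)) {
    return(list(.frame = TRUE, data = lapply(unclass(x), identity)))
  }
  if (is.list(x)) {
    cls <- setdiff(class(x), "list")
    out <- lapply(unclass(x), unclass_deep)
    if (length(cls)) out[[".s3"]] <- cls
    return(out)
  }
  x
}

relist_result <- function(x) {
  if (!is.list(x)) return(x)
  if (isTRUE(x$.matrix)) {
    m <- matrix(unlist(x$data), nrow = x$dim[[1]], ncol = x$dim[[2]])
    if (!is.null(x$dimnames) && length(x$dimnames))
      dimnames(m) <- x$dimnames
    return(m)
  }
  if (isTRUE(x$.frame))
    return(as.data.frame(x$data, stringsAsFactors = FALSE))
  cls <- x$.s3
  x$.s3 <- NULL
  out <- lapply(x, relist_result)
  if (!is.null(cls)) class(out) <- cls
  out
}
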