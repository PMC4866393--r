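# Expression matrix container and TSV/GMT input-output.
#
# The whole pipeline operates on a single container: a genes x samples
# numeric matrix with per-sample metadata carrying a region label, an age
# label and a two-level developmental window (e.g. prenatal/postnatal).

WINDOW_LEVELS_DEFAULT <- c("prenatal", "postnatal")

#' Construct an expression matrix with sample metadata
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param samples data.frame with columns `sample_id`, `region`, `age`,
#'   `window`; one row per column of `values`, in the same order.
#' @param check validate invariants (unique gene ids, finite values,
#'   two-level window). Values may be negative: the simulator emits
#'   log-scale data.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` and `samples`.
#' @export
expression_matrix <- function(values, samples, check = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (check) {
    need <- c("sample_id", "region", "age", "window")
    miss <- setdiff(need, names(samples))
    if (length(miss))
      stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
    if (is.null(rownames(values)))
      stop("expression values must carry gene ids as rownames")
    if (anyDuplicated(rownames(values)))
      stop("duplicate gene ids: ",
           paste(unique(rownames(values)[duplicated(rownames(values))]),
                 collapse = ", "))
    if (ncol(values) != nrow(samples))
      stop("column count (", ncol(values), ") does not match metadata rows (",
           nrow(samples), ")")
    if (!all(is.finite(values)))
      stop("expression values must be finite")
    wl <- unique(as.character(samples$window))
    if (any(is.na(samples$window)) || length(wl) > 2L)
      stop("window must be a two-level factor without missing values; got: ",
           paste(wl, collapse = ", "))
    if (!is.null(colnames(values)) &&
        !identical(colnames(values), as.character(samples$sample_id)))
      stop("column names do not match metadata sample ids")
  }
  colnames(values) <- as.character(samples$sample_id)
  structure(list(values = values, samples = samples),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  regions:", paste(unique(x$samples$region), collapse = ", "), "\n")
  cat("  windows:", paste(unique(x$samples$window), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(E) rownames(E$values)

# Subset helper preserving metadata alignment.
subset_expression <- function(E, genes = NULL, samples = NULL) {
  v <- E$values
  s <- E$samples
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    s <- s[samples, , drop = FALSE]
    rownames(s) <- NULL
  }
  expression_matrix(v, s, check = FALSE)
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The expression file is tab-separated with gene ids in the first column and
#' a header row of sample ids; the metadata file has columns `sample_id`,
#' `region`, `age`, `window`. Samples are reordered to match the metadata.
#'
#' @param matrix_path,metadata_path file paths.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file must have gene id + >=1 sample")
  gid <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(vals)[which(bad)[1]]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[which(bad)[1]]]))))[1]
    stop("non-numeric expression value in column '", col, "', data row ",
         row %||% NA)
  }
  vals <- as.matrix(vals)
  rownames(vals) <- gid
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  missing_in_meta <- setdiff(colnames(vals), meta$sample_id)
  missing_in_mat <- setdiff(meta$sample_id, colnames(vals))
  if (length(missing_in_meta) || length(missing_in_mat))
    stop("sample ids do not match between matrix and metadata; ",
         "absent from metadata: [",
         paste(missing_in_meta, collapse = ", "),
         "]; absent from matrix: [",
         paste(missing_in_mat, collapse = ", "), "]")
  vals <- vals[, meta$sample_id, drop = FALSE]
  expression_matrix(vals, meta)
}

#' Write an expression matrix (and metadata) to TSV
#'
#' Full `%.17g` precision so that a write/read round trip reproduces values
#' exactly.
#'
#' @param E an [expression_matrix()].
#' @param matrix_path,metadata_path output file paths.
#' @export
write_expression <- function(E, matrix_path, metadata_path) {
  df <- data.frame(gene_id = gene_ids(E),
                   format(E$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(E$values))
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(E$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' Drop genes with zero variance across all samples
#'
#' Removes genes whose value is identical in every sample, the minimal filter
#' applied before any correlation-based analysis. Variance is taken across
#' the full sample set jointly; strata formed later may still contain
#' within-stratum constant genes, which the coexpression step flags
#' separately.
#'
#' @param E an [expression_matrix()].
#' @return the filtered expression matrix, original gene order preserved.
#' @export
filter_zero_variance <- function(E) {
  stopifnot(inherits(E, "ExpressionMatrix"), nrow(E$values) > 0)
  v <- matrixStats_rowVars(E$values)
  keep <- v > 0
  if (!any(keep)) stop("no genes survive variance filter")
  subset_expression(E, genes = which(keep))
}

# Row variances without extra dependencies.
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

#' Partition samples into groups
#'
#' @param E an [expression_matrix()].
#' @param by grouping key: `"window"`, `"region"` or `"region_window"`.
#' @return named list of [expression_matrix()] objects; the groups are a
#'   disjoint, exhaustive cover of the input samples and preserve
#'   within-group sample order.
#' @export
split_samples <- function(E, by = c("window", "region", "region_window")) {
  by <- match.arg(by)
  key <- switch(by,
                window = as.character(E$samples$window),
                region = as.character(E$samples$region),
                region_window = paste(E$samples$region, E$samples$window,
                                      sep = "."))
  idx <- split(seq_len(ncol(E$values)), key)
  lapply(idx, function(i) subset_expression(E, samples = i))
}
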