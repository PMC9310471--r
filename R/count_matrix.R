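#' Construct a count matrix with per-cell metadata
#'
#' Bundles a sparse non-negative integer gene-by-cell count matrix with the
#' per-cell annotations the pipeline needs: cluster (cell type) label, age
#' group and sample of origin.
#'
#' @param counts gene-by-cell matrix of non-negative integers; coerced to a
#'   sparse `dgCMatrix`. Row names are gene symbols, column names cell ids;
#'   both must be unique.
#' @param cell_meta data.frame with one row per cell, columns `cell_id`,
#'   `cluster`, `age_group`, `sample_id` (extra columns are kept).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `cell_meta`.
#' @export
count_matrix <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene names in count matrix")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate cell ids in count matrix")
  if (!is_count_like(counts))
    stopf("counts must be non-negative integers")
  cell_meta <- as.data.frame(cell_meta)
  need <- c("cell_id", "cluster", "age_group", "sample_id")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss))
    stopf("cell_meta missing column(s): %s", paste(miss, collapse = ", "))
  if (!identical(as.character(cell_meta$cell_id), colnames(counts)))
    stopf("cell_meta$cell_id must match count matrix column names in order")
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  clusters: %s\n",
              paste(sort(unique(x$cell_meta$cluster)), collapse = ", ")))
  cat(sprintf("  age groups: %s\n",
              paste(sort(unique(x$cell_meta$age_group)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Library-size normalize and log-transform counts
#'
#' Each cell is scaled to a common total (`scale` counts, default 1e4) and
#' log-transformed with a pseudocount of 1:
#' `value[g, c] = ln(1 + scale * counts[g, c] / total[c])`.
#' Zeros stay zero, so sparsity is preserved.
#'
#' @param x a [count_matrix].
#' @param scale target total per cell, default `1e4`.
#' @return A `norm_matrix`: list with the sparse `values` matrix, the
#'   `cell_meta` carried over, and the `scale`/`pseudocount` provenance.
#' @export
normalize_counts <- function(x, scale = 1e4) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0))
    stopf("cell(s) with zero total counts: %s",
          paste(head(colnames(x$counts)[totals == 0], 5), collapse = ", "))
  v <- x$counts
  # operate on the nonzero slots column-wise: x@x holds values column-major
  reps <- diff(v@p)
  v@x <- log1p(scale * v@x / rep(totals, reps))
  structure(list(values = v, cell_meta = x$cell_meta,
                 scale = scale, pseudocount = 1),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d genes x %d cells (scale %g, log1p)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)
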