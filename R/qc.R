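#' Quality-control parameters
#'
#' Cells are removed when their detected-gene count is below `min_genes` or
#' above `max_genes`, or when their mitochondrial fraction exceeds
#' `max_mito_fraction`. The bounds themselves are kept (removal criteria are
#' strict inequalities: fewer than 200, more than 2500, more than 10%).
#'
#' @param min_genes lower detected-gene bound (kept), default 200.
#' @param max_genes upper detected-gene bound (kept), default 2500.
#' @param max_mito_fraction mitochondrial-fraction bound (kept), default 0.10.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_genes = 200, max_genes = 2500,
                      max_mito_fraction = 0.10) {
  stopifnot(min_genes > 0, min_genes < max_genes,
            max_mito_fraction > 0, max_mito_fraction < 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_params")
}

#' Filter low-quality cells
#'
#' Retains exactly the cells with detected-gene count inside
#' `[min_genes, max_genes]` and mitochondrial fraction at most
#' `max_mito_fraction`. Mitochondrial genes are recognized by the mouse
#' naming convention (`mt-` prefix). Genes and cell order are unchanged;
#' the operation is idempotent.
#'
#' @param x a [count_matrix] of raw integer counts.
#' @param params a [qc_params()].
#' @return the filtered [count_matrix].
#' @export
qc_filter <- function(x, params = qc_params()) {
  stopifnot(inherits(x, "count_matrix"), inherits(params, "qc_params"))
  if (!is_count_like(x$counts))
    stopf("qc_filter requires raw integer counts")
  detected <- Matrix::colSums(x$counts > 0)
  totals <- Matrix::colSums(x$counts)
  mito <- grepl("^mt-", rownames(x$counts))
  mito_frac <- if (any(mito))
    Matrix::colSums(x$counts[mito, , drop = FALSE]) / pmax(totals, 1)
  else rep(0, ncol(x$counts))
  keep <- detected >= params$min_genes & detected <= params$max_genes &
    mito_frac <= params$max_mito_fraction
  if (!any(keep))
    stopf("qc_filter removed every cell (no cell satisfies the bounds)")
  count_matrix(x$counts[, keep, drop = FALSE],
               x$cell_meta[keep, , drop = FALSE])
}
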