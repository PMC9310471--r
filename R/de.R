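# Wilcoxon rank-sum differential expression with Bonferroni correction.
# The two-sided test is exact (full enumeration of rank assignments) for
# small tie-free samples and a tie-corrected, continuity-corrected normal
# approximation otherwise.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by complete enumeration of all `choose(n_x + n_y, n_x)` rank
#' assignments when the combined sample size is at most `exact_max` and the
#' data are tie-free; otherwise a normal approximation with tie-corrected
#' variance and continuity correction. The statistic returned is the rank
#' sum of `x`.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` (default) selects it automatically.
#' @param exact_max combined-size cutoff for automatic exactness, default 12.
#' @return list with `statistic` (rank sum of `x`), `p` (two-sided) and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_de <- function(x, y, exact = NULL, exact_max = 12L) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  v <- c(x, y)
  r <- rank(v)
  w <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(v) > 0
  use_exact <- if (is.null(exact)) (n <= exact_max && !ties) else isTRUE(exact)
  if (use_exact && ties)
    stopf("exact Wilcoxon enumeration requires tie-free data")
  if (use_exact) {
    sums <- colSums(matrix(r[combn(n, nx)], nrow = nx))
    p <- min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
    return(list(statistic = w, p = p, method = "exact"))
  }
  mu <- nx * (n + 1) / 2
  tie_tab <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = w, p = 1, method = "normal"))
  d <- w - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  list(statistic = w, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Differential expression table for one contrast
#'
#' Per-gene two-sided Wilcoxon rank-sum p-values between two cell groups on
#' log-normalized expression, Bonferroni-adjusted over the genes actually
#' tested. Fold change is computed on the de-logged scale:
#' `log2fc = log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))`.
#' A gene is called `up` when `p_adj < 0.05` and `log2fc > 0.1`, `down` when
#' `p_adj < 0.05` and `log2fc < -0.1`, otherwise `ns`.
#'
#' @param norm a `norm_matrix` (see [normalize_counts()]).
#' @param labels character vector of per-cell group labels (length =
#'   number of cells).
#' @param group_a,group_b label values defining the contrast (`a` vs `b`;
#'   positive log2fc means higher in `a`).
#' @param min_pct detection-fraction prefilter: only genes detected in at
#'   least this fraction of cells in either group are tested (and enter the
#'   Bonferroni denominator). Set to 0 to test every gene.
#' @param alpha adjusted-p significance threshold for direction calls.
#' @param lfc_threshold absolute log2 fold-change threshold for direction
#'   calls.
#' @return data.frame of class `deg_table`, sorted by raw p then
#'   `|log2fc|` descending then gene name, with columns `gene`, `log2fc`,
#'   `p_raw`, `p_adj`, `mean_a`, `mean_b`, `pct_a`, `pct_b`, `direction`.
#'   Attribute `n_tested` records the Bonferroni denominator.
#' @export
deg_table <- function(norm, labels, group_a, group_b, min_pct = 0.1,
                      alpha = 0.05, lfc_threshold = 0.1) {
  stopifnot(inherits(norm, "norm_matrix"))
  labels <- as.character(labels)
  if (length(labels) != ncol(norm$values))
    stopf("labels length (%d) != number of cells (%d)",
          length(labels), ncol(norm$values))
  ia <- which(labels == group_a)
  ib <- which(labels == group_b)
  if (length(ia) < 3 || length(ib) < 3)
    stopf("both groups need >= 3 cells (a: %d, b: %d)", length(ia), length(ib))
  if (length(intersect(ia, ib)))
    stopf("groups overlap")

  # cells x genes orientation makes per-gene column access cheap
  va <- Matrix::t(norm$values[, ia, drop = FALSE])
  vb <- Matrix::t(norm$values[, ib, drop = FALSE])
  pct_a <- Matrix::colSums(va > 0) / nrow(va)
  pct_b <- Matrix::colSums(vb > 0) / nrow(vb)
  mean_a <- Matrix::colSums(expm1(va)) / nrow(va)
  mean_b <- Matrix::colSums(expm1(vb)) / nrow(vb)

  tested <- which(pct_a >= min_pct | pct_b >= min_pct)
  m <- length(tested)
  if (!m) stopf("no gene passes the detection prefilter")

  da <- as.matrix(va[, tested, drop = FALSE])
  db <- as.matrix(vb[, tested, drop = FALSE])
  p_raw <- vapply(seq_len(m), function(k)
    wilcoxon_de(da[, k], db[, k], exact = FALSE)$p, numeric(1))

  genes <- rownames(norm$values)[tested]
  lfc <- log2((mean_a[tested] + 1) / (mean_b[tested] + 1))
  p_adj <- pmin(1, p_raw * m)
  direction <- rep("ns", m)
  direction[p_adj < alpha & lfc > lfc_threshold] <- "up"
  direction[p_adj < alpha & lfc < -lfc_threshold] <- "down"

  out <- data.frame(gene = genes, log2fc = lfc, p_raw = p_raw, p_adj = p_adj,
                    mean_a = mean_a[tested], mean_b = mean_b[tested],
                    pct_a = pct_a[tested], pct_b = pct_b[tested],
                    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, -abs(out$log2fc), out$gene), ]
  rownames(out) <- NULL
  attr(out, "n_tested") <- m
  attr(out, "panel") <- rownames(norm$values)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  class(out) <- c("deg_table", "data.frame")
  out
}
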