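# Dimensionality reduction and graph clustering: supporting plumbing used to
# reproduce cluster labels when none are supplied. Interaction-stage analyses
# normally consume the labels carried in cell metadata.

#' Reduce dimensionality and cluster cells
#'
#' Selects highly variable genes by dispersion (variance/mean on the de-logged
#' scale), standardizes each gene (values clipped at +/-10), projects cells
#' onto the top principal components, builds a k-nearest-neighbour graph in
#' PC space and partitions it by Louvain community detection.
#'
#' @param norm a `norm_matrix`.
#' @param n_hvg number of highly variable genes, default 500.
#' @param n_pcs number of principal components, default 20.
#' @param resolution Louvain resolution, default 1.
#' @param k neighbours per cell for the kNN graph, default 20.
#' @param seed integer seed (community detection is stochastic).
#' @return integer cluster labels named by cell id.
#' @export
reduce_and_cluster <- function(norm, n_hvg = 500, n_pcs = 20, resolution = 1,
                               k = 20, seed = 1L) {
  stopifnot(inherits(norm, "norm_matrix"))
  v <- norm$values
  n_cells <- ncol(v)
  if (n_cells < n_pcs + 1)
    stopf("need at least n_pcs + 1 = %d cells, have %d", n_pcs + 1, n_cells)
  if (n_hvg > nrow(v))
    stopf("n_hvg (%d) exceeds gene count (%d)", n_hvg, nrow(v))

  ex <- expm1(v)
  mu <- Matrix::rowMeans(ex)
  m2 <- Matrix::rowMeans(ex^2)
  disp <- ifelse(mu > 0, (m2 - mu^2) * n_cells / pmax(n_cells - 1, 1) / mu, 0)
  hvg <- order(disp, decreasing = TRUE)[seq_len(n_hvg)]

  x <- t(as.matrix(v[hvg, , drop = FALSE]))   # cells x genes
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  x <- pmin(pmax(sweep(sweep(x, 2, ctr), 2, sds, "/"), -10), 10)

  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  pcs <- prcomp(x, rank. = n_pcs, center = FALSE, scale. = FALSE)$x

  # kNN by blocked squared-Euclidean distance (keeps memory bounded)
  k <- min(k, n_cells - 1L)
  sq <- rowSums(pcs^2)
  nn <- matrix(0L, n_cells, k)
  bs <- 512L
  for (s in seq(1L, n_cells, by = bs)) {
    idx <- s:min(s + bs - 1L, n_cells)
    d <- outer(sq[idx], sq, "+") - 2 * tcrossprod(pcs[idx, , drop = FALSE], pcs)
    for (j in seq_along(idx)) {
      d[j, idx[j]] <- Inf
      nn[idx[j], ] <- order(d[j, ])[seq_len(k)]
    }
  }
  edges <- cbind(rep(seq_len(n_cells), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(derive_seed(seed, "louvain"), {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  setNames(as.integer(memb), colnames(v))
}
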