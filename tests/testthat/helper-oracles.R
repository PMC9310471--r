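# Independent oracles and fixture builders shared across test files. These
# re-derive expected values by the most direct route available (explicit
# loops, closed forms, exhaustive enumeration) and deliberately share no code
# with the implementation they check.

# Step-by-step GSEA running sum: literal loop over the ranked list.
brute_es <- function(metric, genes, gene_set, p = 1) {
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  wsum <- sum(abs(metric[hit])^p)
  run <- 0; best_pos <- 0; best_neg <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) {
      if (wsum > 0) abs(metric[i])^p / wsum else 1 / nh
    } else {
      -1 / (n - nh)
    }
    best_pos <- max(best_pos, run)
    best_neg <- min(best_neg, run)
  }
  # signed max deviation; the positive extremum wins exact ties
  unname(if (best_pos >= -best_neg) best_pos else best_neg)
}

# Exhaustive two-sided Wilcoxon p by enumerating every assignment of ranks.
brute_wilcox_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  sums <- apply(combn(n, length(x)), 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums <= w_obs), mean(sums >= w_obs)))
}

# Exhaustive permutation null for the product-of-cluster-means statistic.
brute_perm_p <- function(va, vb, ns, nr, t_obs) {
  n <- length(va)
  tn <- c()
  for (j in seq_len(ncol(combn(n, ns)))) {
    s <- combn(n, ns)[, j]
    rest <- setdiff(seq_len(n), s)
    for (k in seq_len(ncol(combn(length(rest), nr)))) {
      r <- rest[combn(length(rest), nr)[, k]]
      tn <- c(tn, mean(va[s]) * mean(vb[r]))
    }
  }
  list(p = (1 + sum(tn >= t_obs)) / (1 + length(tn)), t_null = tn)
}

# Upper-tail hypergeometric p by summing the density over overlap values.
brute_hyper_p <- function(k, term_size, deg_size, bg) {
  kmax <- min(term_size, deg_size)
  sum(stats::dhyper(k:kmax, term_size, bg - term_size, deg_size))
}

# Build a deg_table-shaped object directly (for interaction/enrichment tests
# that need exact control over fold changes and p-values).
make_deg <- function(gene, log2fc, p_raw, mean_a = 1, mean_b = 1,
                     direction = NULL, panel = gene) {
  m <- length(gene)
  p_adj <- pmin(1, p_raw * m)
  if (is.null(direction)) {
    direction <- rep("ns", m)
    direction[p_adj < 0.05 & log2fc > 0.1] <- "up"
    direction[p_adj < 0.05 & log2fc < -0.1] <- "down"
  }
  out <- data.frame(gene = gene, log2fc = log2fc, p_raw = p_raw,
                    p_adj = p_adj, mean_a = rep_len(mean_a, m),
                    mean_b = rep_len(mean_b, m),
                    pct_a = rep(1, m), pct_b = rep(1, m),
                    direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "n_tested") <- m
  attr(out, "panel") <- panel
  class(out) <- c("deg_table", "data.frame")
  out
}

# Wrap a plain dense matrix as a norm_matrix (values taken as already
# log-normalized).
make_norm <- function(m) {
  structure(list(values = Matrix::Matrix(m, sparse = TRUE),
                 scale = 1e4, pseudocount = 1),
            class = "norm_matrix")
}

# Random DE table used by enrichment tests.
ranked_fixture <- function(n = 20, seed = 11) {
  set.seed(seed)
  make_deg(sprintf("g%03d", 1:n), rnorm(n), runif(n, 1e-6, 1))
}

# Small two-type simulation reused by several files.
small_sim <- function(seed = 1, n = 80, decoys = list(low_genes = 0,
                                                      high_genes = 0,
                                                      high_mito = 0)) {
  generate_counts(sim_config(
    cell_types = c(microglia = n, tcm = n),
    n_background_genes = 150, n_markers_per_type = 5,
    qc_decoys = decoys, seed = seed))
}
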