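# Enrichment module: preranked GSEA (classic weighted Kolmogorov-Smirnov
# running sum, gene-label permutation null, GSEA-style FDR), hypergeometric
# term enrichment and gene-set activation z-scores.

#' Build a preranked gene list from a DE table
#'
#' Ranking metric: `sign(log2fc) * (-log10 p_raw)` (p-values of zero are
#' floored at the smallest positive double). Ties are broken by log2 fold
#' change, then gene name, so the output order is strict and deterministic.
#'
#' @param deg a [deg_table].
#' @return named numeric vector (class `ranked_list`), metric values sorted
#'   descending; names are gene symbols, no duplicates.
#' @export
rank_genes <- function(deg) {
  if (!nrow(deg)) stopf("empty DE table")
  p <- pmax(deg$p_raw, .Machine$double.xmin)
  metric <- sign(deg$log2fc) * (-log10(p))
  ord <- order(-metric, -deg$log2fc, deg$gene)
  structure(setNames(metric[ord], deg$gene[ord]), class = "ranked_list")
}

#' GSEA enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walking down the ranked list, set members increment the running sum by
#' `|metric|^p` normalized by the sum over members; non-members decrement it
#' by `1/(N - N_hit)`. The enrichment score is the signed maximum deviation
#' from zero; the leading edge contains the members at or before the
#' extremum (positive ES) or at or after it (negative ES).
#'
#' @param ranked a [rank_genes()] result (named metric vector, descending).
#' @param gene_set character vector; must intersect the ranked genes.
#' @param p weighting exponent, default 1 (0 recovers the unweighted KS
#'   statistic).
#' @return list with `es` (in `[-1, 1]`), `leading_edge` and the hit
#'   positions (`hits`).
#' @export
gsea_es <- function(ranked, gene_set, p = 1) {
  genes <- names(ranked)
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stopf("gene set does not intersect the ranked list")
  w <- abs(unclass(ranked))^p
  w[!hit] <- 0
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else ifelse(hit, 1 / nh, 0)
  dec <- if (n > nh) 1 / (n - nh) else 0
  run <- cumsum(ifelse(hit, inc, -dec))
  i_max <- which.max(run); i_min <- which.min(run)
  es <- if (run[i_max] >= -run[i_min]) run[i_max] else run[i_min]
  le <- if (es >= 0) genes[seq_len(i_max)][hit[seq_len(i_max)]]
        else genes[i_min:n][hit[i_min:n]]
  list(es = es, leading_edge = le, hits = which(hit))
}

# ES from sorted hit positions only: O(n_hits) per evaluation, used for the
# permutation null. Identical to gsea_es by construction (tested).
es_from_positions <- function(pos, wabs, n) {
  pos <- sort(pos)
  s <- length(pos)
  w <- wabs[pos]
  sw <- sum(w)
  inc <- if (sw > 0) cumsum(w) / sw else seq_len(s) / s
  dec <- if (n > s) 1 / (n - s) else 0
  after <- inc - (pos - seq_len(s)) * dec       # running sum just after hit k
  before <- c(0, inc[-s]) - (pos - seq_len(s)) * dec  # just before hit k
  hi <- max(after, 0)
  lo <- min(before, if (n > s) -(n - pos[s]) * dec + inc[s] else 0, 0)
  # the global minimum over miss stretches occurs just before some hit or at
  # the end of the list; the global maximum just after some hit (or 0).
  if (hi >= -lo) hi else lo
}

#' Preranked GSEA with permutation NES and FDR
#'
#' The null for each set is built from `n_perm` random gene-label sets of
#' matched size drawn from the ranked genes. `NES = ES / mean(|ES_null|)`
#' over same-sign null values; the nominal p is the add-one tail proportion
#' of the same-sign null. FDR q follows the GSEA procedure: the ratio of the
#' pooled-null tail fraction to the observed tail fraction on the NES scale,
#' floored at the smallest attainable nominal p and capped at 1.
#'
#' @param ranked a [rank_genes()] result.
#' @param gene_sets named list of character vectors; every set must
#'   intersect the ranked genes.
#' @param n_perm permutations, default 1000.
#' @param seed integer seed; identical seeds give identical results.
#' @param p weighting exponent passed to [gsea_es()].
#' @return data.frame of class `gsea_result`: `term`, `size`, `es`, `nes`,
#'   `p_nominal`, `fdr_q`, `leading_edge` (list column).
#' @export
gsea_nes_fdr <- function(ranked, gene_sets, n_perm = 1000, seed = 1L, p = 1) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (!length(gene_sets)) stopf("no gene sets supplied")
  genes <- names(ranked)
  n <- length(genes)
  wabs <- abs(unclass(ranked))^p

  obs <- lapply(gene_sets, function(gs) gsea_es(ranked, gs, p = p))
  sizes <- vapply(obs, function(o) length(o$hits), 0L)

  null_by_size <- with_seed(derive_seed(seed, "gsea_null"), {
    out <- list()
    for (s in sort(unique(sizes)))
      out[[as.character(s)]] <- vapply(seq_len(n_perm), function(i)
        es_from_positions(sample.int(n, s), wabs, n), numeric(1))
    out
  })

  es <- vapply(obs, `[[`, numeric(1), "es")
  nes <- numeric(length(es)); p_nom <- numeric(length(es))
  nes_null <- vector("list", length(es))
  for (i in seq_along(es)) {
    nul <- null_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(nul[nul >= 0]); neg_mean <- mean(abs(nul[nul < 0]))
    same <- if (es[i] >= 0) nul[nul >= 0] else nul[nul < 0]
    denom <- if (es[i] >= 0) pos_mean else neg_mean
    nes[i] <- if (is.finite(denom) && denom > 0) es[i] / denom else 0
    p_nom[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    # normalize the whole null of this size to the NES scale for the FDR
    nn <- nul
    nn[nul >= 0] <- if (is.finite(pos_mean) && pos_mean > 0)
      nul[nul >= 0] / pos_mean else 0
    nn[nul < 0] <- if (is.finite(neg_mean) && neg_mean > 0)
      nul[nul < 0] / neg_mean else 0
    nes_null[[i]] <- nn
  }
  pool <- unlist(nes_null)
  fdr <- vapply(seq_along(nes), function(i) {
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (!is.finite(num)) num <- 1
    q <- if (den > 0) num / den else 1
    min(1, max(q, 1 / (n_perm + 1)))
  }, numeric(1))

  out <- data.frame(term = names(gene_sets), size = sizes, es = es,
                    nes = nes, p_nominal = p_nom, fdr_q = fdr,
                    stringsAsFactors = FALSE)
  out$leading_edge <- I(lapply(obs, `[[`, "leading_edge"))
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Hypergeometric term over-representation p-value
#'
#' One-sided upper-tail probability of observing at least the given overlap
#' between a DEG list and a term, both drawn from a background of
#' `background_size` genes.
#'
#' @param deg_genes character vector of DEG symbols.
#' @param term character vector of term-annotated symbols.
#' @param background_size total genes in the background universe.
#' @return p-value in `(0, 1]`.
#' @export
term_enrichment <- function(deg_genes, term, background_size) {
  deg_genes <- unique(deg_genes); term <- unique(term)
  if (length(term) > background_size || length(deg_genes) > background_size)
    stopf("term or DEG list larger than the background")
  k <- length(intersect(deg_genes, term))
  phyper(k - 1, length(term), background_size - length(term),
         length(deg_genes), lower.tail = FALSE)
}

#' Activation z-score of a functional term
#'
#' Counts the DEGs annotated to the term by direction and scores the
#' predicted activation direction as `z = (n_up - n_down) / sqrt(n_up +
#' n_down)`. A term is flagged significant when `|z| > 2` and the
#' hypergeometric enrichment p is below 0.05. With no annotated DEGs the
#' z-score is undefined (`NA`) and the term is not significant.
#'
#' @param term character vector of term-annotated gene symbols.
#' @param deg a [deg_table].
#' @param background_size background universe size for the enrichment p;
#'   defaults to the number of genes in `deg`.
#' @return one-row data.frame of class `zscore_result`: `n_annotated_degs`,
#'   `n_up`, `n_down`, `z`, `p_enrich`, `significant`.
#' @export
activation_z <- function(term, deg, background_size = nrow(deg)) {
  stopifnot(inherits(deg, "deg_table"))
  deg_sig <- deg[deg$direction != "ns", , drop = FALSE]
  in_term <- deg_sig$gene %in% term
  n_up <- sum(in_term & deg_sig$direction == "up")
  n_down <- sum(in_term & deg_sig$direction == "down")
  n_ann <- n_up + n_down
  z <- if (n_ann > 0) (n_up - n_down) / sqrt(n_ann) else NA_real_
  p_enrich <- term_enrichment(deg_sig$gene, intersect(term, deg$gene),
                              background_size)
  out <- data.frame(n_annotated_degs = n_ann, n_up = n_up, n_down = n_down,
                    z = z, p_enrich = p_enrich,
                    significant = !is.na(z) && abs(z) > 2 && p_enrich < 0.05)
  class(out) <- c("zscore_result", "data.frame")
  out
}
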