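# Gene-pair interaction core: enumerate ligand-receptor pairs between a
# sender and a receiver cell type from their DE tables and an annotated
# gene-pair database, score them, and assess significance by cluster-label
# permutation. Pair direction is always sender (gene_a, ligand side) to
# receiver (gene_b).

#' Enumerate candidate ligand-receptor pairs
#'
#' A database record `(gene_a, gene_b)` is emitted when `gene_a` passes the
#' direction filter in the sender DE table and `gene_b` passes it in the
#' receiver DE table. Database genes absent from the expression panel are
#' skipped with a warning (reference databases are supersets of any panel).
#'
#' @param deg_sender,deg_receiver [deg_table] objects from the same
#'   normalization run.
#' @param db an `interaction_db` data.frame.
#' @param direction_filter `"up"` (default; the direction plotted in the
#'   source figures), `"down"` or `"any"` (any tested gene qualifies).
#' @param sender_type,receiver_type cell-type names recorded on each row.
#' @return data.frame of class `pair_result`, ordered by sender gene then
#'   receiver gene, with per-pair fold changes, group means, `power_sum`
#'   (log2fc_a + log2fc_b), `power_product` (mean_a * mean_b), noisy-OR
#'   `confidence`, `action_effect`, `terms` and a `perm_p` column of `NA`
#'   until [permutation_test()] fills it.
#' @export
enumerate_pairs <- function(deg_sender, deg_receiver, db,
                            direction_filter = c("up", "down", "any"),
                            sender_type = "sender",
                            receiver_type = "receiver") {
  direction_filter <- match.arg(direction_filter)
  stopifnot(inherits(deg_sender, "deg_table"),
            inherits(deg_receiver, "deg_table"))
  passes <- function(tab) {
    if (direction_filter == "any") tab$gene
    else tab$gene[tab$direction == direction_filter]
  }
  panel <- union(attr(deg_sender, "panel") %||% deg_sender$gene,
                 attr(deg_receiver, "panel") %||% deg_receiver$gene)
  absent <- setdiff(union(db$gene_a, db$gene_b), panel)
  if (length(absent))
    warning(sprintf("%d database gene(s) absent from the expression panel; %s",
                    length(absent), "their records are skipped"),
            call. = FALSE)
  keep <- db$gene_a %in% passes(deg_sender) &
    db$gene_b %in% passes(deg_receiver)
  hits <- db[keep, , drop = FALSE]
  ia <- match(hits$gene_a, deg_sender$gene)
  ib <- match(hits$gene_b, deg_receiver$gene)
  conf <- combine_confidence(cbind(hits$confidence_experimental,
                                   hits$confidence_database,
                                   hits$confidence_textmining))
  out <- data.frame(
    sender_type = rep(sender_type, nrow(hits)),
    receiver_type = rep(receiver_type, nrow(hits)),
    gene_a = hits$gene_a, gene_b = hits$gene_b,
    log2fc_a = deg_sender$log2fc[ia], log2fc_b = deg_receiver$log2fc[ib],
    mean_a = deg_sender$mean_a[ia], mean_b = deg_receiver$mean_a[ib],
    power_sum = deg_sender$log2fc[ia] + deg_receiver$log2fc[ib],
    power_product = deg_sender$mean_a[ia] * deg_receiver$mean_a[ib],
    confidence = conf,
    action_effect = hits$action_effect,
    terms = hits$terms,
    perm_p = rep(NA_real_, nrow(hits)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_result", "data.frame")
  out
}

#' Pair power score
#'
#' Two conventions: `sum_lfc` (the sum of the two genes' log2 fold changes)
#' and `product_expr` (the product of their mean expression levels).
#'
#' @param pairs a `pair_result` data.frame (or any data.frame with the
#'   required columns).
#' @param mode `"sum_lfc"` or `"product_expr"`.
#' @return numeric vector, one score per pair.
#' @export
score_power <- function(pairs, mode = c("sum_lfc", "product_expr")) {
  mode <- match.arg(mode)
  if (mode == "sum_lfc") pairs$log2fc_a + pairs$log2fc_b
  else pairs$mean_a * pairs$mean_b
}

#' Aggregate evidence-channel confidences (noisy-OR)
#'
#' `1 - prod(1 - c_i)` across channels: monotone non-decreasing in every
#' channel, equal to the single channel when only one is given, and absorbed
#' by any channel at 1.
#'
#' @param channels numeric vector of confidences in `[0, 1]`, or a matrix
#'   with one row per record and one column per channel.
#' @return a single confidence in `[0, 1]` (or one per row of a matrix).
#' @export
combine_confidence <- function(channels) {
  if (is.matrix(channels)) {
    if (any(channels < 0 | channels > 1))
      stopf("confidence channels must lie in [0, 1]")
    return(1 - apply(1 - channels, 1, prod))
  }
  if (!length(channels)) stopf("need at least one confidence channel")
  if (any(channels < 0 | channels > 1))
    stopf("confidence channels must lie in [0, 1]")
  1 - prod(1 - channels)
}

#' Cluster-label permutation test for one gene pair
#'
#' The observed statistic is the product of cluster means,
#' `T = mean(norm[gene_a, sender cells]) * mean(norm[gene_b, receiver
#' cells])`. The null is built by jointly shuffling the cluster labels of all
#' cells `n_perm` times and recomputing `T`; the one-sided, upper-tail,
#' add-one p-value is `(1 + #(T_perm >= T_obs)) / (1 + n_perm)`, so the
#' smallest attainable value is `1/(n_perm + 1)`.
#'
#' @param norm a `norm_matrix`.
#' @param labels per-cell cluster labels.
#' @param sender_type,receiver_type label values selecting the two clusters.
#' @param gene_a,gene_b gene symbols (sender ligand, receiver receptor).
#' @param n_perm number of permutations, default 1000.
#' @param seed integer seed.
#' @param exhaustive enumerate every distinct assignment of cells to the
#'   (sender, receiver, rest) partition instead of sampling; only feasible
#'   for a handful of cells.
#' @return list with `p`, `t_obs`, `t_null` (the null statistics) and
#'   `n_perm`.
#' @export
permutation_test <- function(norm, labels, sender_type, receiver_type,
                             gene_a, gene_b, n_perm = 1000, seed = 1L,
                             exhaustive = FALSE) {
  stopifnot(inherits(norm, "norm_matrix"), n_perm >= 1)
  labels <- as.character(labels)
  if (length(labels) != ncol(norm$values))
    stopf("labels length != number of cells")
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(norm$values)) stopf("gene %s absent from matrix", g)
  is_s <- labels == sender_type
  is_r <- labels == receiver_type
  if (!any(is_s)) stopf("no cells labelled %s", sender_type)
  if (!any(is_r)) stopf("no cells labelled %s", receiver_type)
  va <- as.numeric(norm$values[gene_a, ])
  vb <- as.numeric(norm$values[gene_b, ])
  ns <- sum(is_s); nr <- sum(is_r); n <- length(labels)
  t_obs <- mean(va[is_s]) * mean(vb[is_r])

  if (exhaustive) {
    sender_sets <- combn(n, ns)
    t_null <- c()
    for (j in seq_len(ncol(sender_sets))) {
      s <- sender_sets[, j]
      rest <- setdiff(seq_len(n), s)
      recv_sets <- combn(length(rest), nr)
      t_null <- c(t_null, apply(recv_sets, 2, function(rr)
        mean(va[s]) * mean(vb[rest[rr]])))
    }
  } else {
    t_null <- with_seed(derive_seed(seed, paste("perm", gene_a, gene_b)), {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, ns + nr)
        mean(va[idx[seq_len(ns)]]) * mean(vb[idx[ns + seq_len(nr)]])
      }, numeric(1))
    })
  }
  p <- (1 + sum(t_null >= t_obs)) / (1 + length(t_null))
  list(p = p, t_obs = t_obs, t_null = t_null, n_perm = length(t_null))
}

#' Restrict pairs to a functional term
#'
#' @param pairs a `pair_result` data.frame.
#' @param term non-empty character vector of gene symbols.
#' @param mode `"both"` keeps pairs with both members in the term,
#'   `"either"` pairs with at least one member. Order is preserved.
#' @return the filtered `pair_result`.
#' @export
term_restrict <- function(pairs, term, mode = c("both", "either")) {
  mode <- match.arg(mode)
  if (!length(term)) stopf("term gene set is empty")
  keep <- if (mode == "both")
    pairs$gene_a %in% term & pairs$gene_b %in% term
  else pairs$gene_a %in% term | pairs$gene_b %in% term
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep pairs with a given annotated action effect
#'
#' @param pairs a `pair_result` data.frame.
#' @param effect `"positive"`, `"negative"` or `"unspecified"`.
#' @return the filtered `pair_result`.
#' @export
filter_effect <- function(pairs,
                          effect = c("positive", "negative", "unspecified")) {
  effect <- match.arg(effect)
  out <- pairs[pairs$action_effect == effect, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize pairs per (sender, receiver) cell-type pair
#'
#' One row per cell-type pair with at least one gene pair: the pair count
#' and the total power under the chosen scoring mode. Ordered by pair count
#' descending (ties by sender then receiver name). The row counts conserve:
#' their sum equals the number of input pairs.
#'
#' @param pairs a `pair_result` data.frame.
#' @param power_mode passed to [score_power()].
#' @return data.frame with `sender_type`, `receiver_type`, `n_pairs`,
#'   `total_power`.
#' @export
summarize_cell_pairs <- function(pairs, power_mode = c("sum_lfc",
                                                       "product_expr")) {
  power_mode <- match.arg(power_mode)
  if (!nrow(pairs))
    return(data.frame(sender_type = character(), receiver_type = character(),
                      n_pairs = integer(), total_power = numeric()))
  pw <- score_power(pairs, power_mode)
  key <- interaction(pairs$sender_type, pairs$receiver_type, drop = TRUE,
                     sep = "\r")
  agg <- data.frame(
    sender_type = tapply(pairs$sender_type, key, `[`, 1),
    receiver_type = tapply(pairs$receiver_type, key, `[`, 1),
    n_pairs = as.integer(tapply(pw, key, length)),
    total_power = as.numeric(tapply(pw, key, sum)),
    stringsAsFactors = FALSE)
  agg <- agg[order(-agg$n_pairs, agg$sender_type, agg$receiver_type), ]
  rownames(agg) <- NULL
  agg
}
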