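#' Fit a sender-to-receiver cell-cell crosstalk model
#'
#' The central analysis: differential expression (old vs young by default)
#' within the sender and the receiver cell type, enumeration of
#' ligand-receptor pairs against the gene-pair database, power scoring,
#' noisy-OR confidence aggregation and cluster-label permutation
#' significance for every emitted pair. Optionally restricts pairs to a
#' functional term and/or an annotated action effect.
#'
#' Two contrast modes are supported: `"age"` compares `age_a` vs `age_b`
#' cells within each cell type (the aging contrast), `"marker"` compares a
#' cell type against all other cells (cluster-marker contrast). The
#' permutation statistic always compares the sender and receiver clusters
#' in the `age_a` (aged) compartment, matching the communication being
#' scored.
#'
#' @param norm a `norm_matrix` of QC-passed, log-normalized expression.
#' @param cell_type per-cell cluster (cell type) labels.
#' @param age_group per-cell age-group labels.
#' @param sender_type,receiver_type cell-type names.
#' @param db an `interaction_db` data.frame.
#' @param contrast `"age"` (default) or `"marker"`.
#' @param age_a,age_b age groups contrasted (defaults `"old"` vs
#'   `"young"`).
#' @param direction_filter DEG direction required on both sides
#'   (see [enumerate_pairs()]).
#' @param power_mode pair scoring convention (see [score_power()]).
#' @param term optional gene set restricting pairs; `term_mode` as in
#'   [term_restrict()].
#' @param term_mode `"both"` or `"either"`.
#' @param effect optional action-effect filter (see [filter_effect()]).
#' @param n_perm permutations per pair, default 1000.
#' @param seed integer seed.
#' @param min_pct DE detection prefilter passed to [deg_table()].
#' @return An object of class `crosstalk`: list with `pairs` (the scored
#'   `pair_result` with `perm_p` filled), `summary` (per cell-type-pair),
#'   the two DE tables, and the call parameters.
#' @examples
#' sim <- generate_counts(sim_config(
#'   cell_types = c(microglia = 60, tcm = 60),
#'   n_background_genes = 60,
#'   qc_decoys = list(low_genes = 0, high_genes = 0, high_mito = 0),
#'   seed = 1))
#' db <- generate_interaction_db(rownames(sim$counts$counts),
#'                               n_decoy_pairs = 5, seed = 1)
#' norm <- normalize_counts(sim$counts)
#' fit <- crosstalk(norm, sim$counts$cell_meta$cluster,
#'                  sim$counts$cell_meta$age_group,
#'                  "microglia", "tcm", db, n_perm = 100, seed = 1)
#' fit
#' @export
crosstalk <- function(norm, cell_type, age_group, sender_type, receiver_type,
                      db, contrast = c("age", "marker"),
                      age_a = "old", age_b = "young",
                      direction_filter = "up",
                      power_mode = c("sum_lfc", "product_expr"),
                      term = NULL, term_mode = "both", effect = NULL,
                      n_perm = 1000, seed = 1L, min_pct = 0.1) {
  contrast <- match.arg(contrast)
  power_mode <- match.arg(power_mode)
  stopifnot(inherits(norm, "norm_matrix"))
  cell_type <- as.character(cell_type)
  age_group <- as.character(age_group)

  deg_for <- function(type) {
    if (contrast == "age") {
      sub <- which(cell_type == type)
      if (!length(sub)) stopf("no cells of type %s", type)
      sn <- norm
      sn$values <- norm$values[, sub, drop = FALSE]
      deg_table(sn, age_group[sub], age_a, age_b, min_pct = min_pct)
    } else {
      deg_table(norm, ifelse(cell_type == type, type, ".rest"),
                type, ".rest", min_pct = min_pct)
    }
  }
  deg_s <- deg_for(sender_type)
  deg_r <- deg_for(receiver_type)

  pairs <- enumerate_pairs(deg_s, deg_r, db, direction_filter,
                           sender_type = sender_type,
                           receiver_type = receiver_type)
  if (!is.null(term)) pairs <- term_restrict(pairs, term, term_mode)
  if (!is.null(effect)) pairs <- filter_effect(pairs, effect)

  # permutation labels: type within the aged compartment for the age
  # contrast, plain cluster labels for the marker contrast
  if (contrast == "age") {
    perm_labels <- paste(cell_type, age_group, sep = "@")
    s_lab <- paste(sender_type, age_a, sep = "@")
    r_lab <- paste(receiver_type, age_a, sep = "@")
  } else {
    perm_labels <- cell_type
    s_lab <- sender_type
    r_lab <- receiver_type
  }
  if (nrow(pairs)) {
    pairs$perm_p <- vapply(seq_len(nrow(pairs)), function(i) {
      permutation_test(norm, perm_labels, s_lab, r_lab,
                       pairs$gene_a[i], pairs$gene_b[i],
                       n_perm = n_perm, seed = seed)$p
    }, numeric(1))
  }

  structure(list(
    pairs = pairs,
    summary = summarize_cell_pairs(pairs, power_mode),
    deg_sender = deg_s, deg_receiver = deg_r,
    sender_type = sender_type, receiver_type = receiver_type,
    contrast = contrast, direction_filter = direction_filter,
    power_mode = power_mode, n_perm = n_perm, seed = seed,
    call = match.call()
  ), class = "crosstalk")
}

#' @export
print.crosstalk <- function(x, ...) {
  cat(sprintf("crosstalk: %s -> %s (%s contrast, %s DEGs, power = %s)\n",
              x$sender_type, x$receiver_type, x$contrast,
              x$direction_filter, x$power_mode))
  cat(sprintf("  %d pair(s), %d with perm_p < 0.05 (n_perm = %d)\n",
              nrow(x$pairs), sum(x$pairs$perm_p < 0.05, na.rm = TRUE),
              x$n_perm))
  if (nrow(x$pairs)) {
    top <- x$pairs[order(-score_power(x$pairs, x$power_mode)), ]
    top <- head(top, 5)
    cat("  top pairs by power:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s -> %s  power_sum %.3f  power_product %.3f  perm_p %.4g\n",
                  top$gene_a[i], top$gene_b[i], top$power_sum[i],
                  top$power_product[i], top$perm_p[i]))
  }
  invisible(x)
}

#' @export
summary.crosstalk <- function(object, ...) {
  res <- list(cell_pairs = object$summary,
              n_pairs = nrow(object$pairs),
              n_significant = sum(object$pairs$perm_p < 0.05, na.rm = TRUE),
              pairs = object$pairs)
  class(res) <- "summary.crosstalk"
  res
}

#' @export
print.summary.crosstalk <- function(x, ...) {
  cat(sprintf("%d pair(s), %d significant at perm_p < 0.05\n",
              x$n_pairs, x$n_significant))
  print(x$cell_pairs)
  invisible(x)
}

#' @export
as.data.frame.crosstalk <- function(x, ...) as.data.frame(x$pairs)

#' Dot plot of fitted crosstalk pairs
#'
#' Pairs along the x axis, power on the y axis, point size proportional to
#' power, colour encoding permutation significance.
#'
#' @param x a `crosstalk` object.
#' @param alpha significance threshold used for colouring, default 0.05.
#' @param ... passed to [graphics::plot()].
#' @export
plot.crosstalk <- function(x, alpha = 0.05, ...) {
  p <- x$pairs
  if (!nrow(p)) {
    graphics::plot.new(); graphics::title("no pairs"); return(invisible(x))
  }
  pw <- score_power(p, x$power_mode)
  lab <- paste(p$gene_a, p$gene_b, sep = "→")
  sig <- !is.na(p$perm_p) & p$perm_p < alpha
  graphics::plot(seq_along(pw), pw, xaxt = "n", pch = 19,
                 cex = 0.8 + 1.8 * (pw - min(pw)) /
                   max(max(pw) - min(pw), .Machine$double.eps),
                 col = ifelse(sig, "firebrick", "grey60"),
                 xlab = "", ylab = sprintf("power (%s)", x$power_mode),
                 main = sprintf("%s → %s", x$sender_type,
                                x$receiver_type), ...)
  graphics::axis(1, at = seq_along(pw), labels = lab, las = 2, cex.axis = 0.7)
  invisible(x)
}
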