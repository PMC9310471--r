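# Interaction core: pair enumeration, scoring, confidence aggregation,
# permutation significance, term/effect filters and summaries.

db_row <- function(a, b, effect = "unspecified", ce = 0.8, cd = 0.5,
                   ct = 0.2, terms = "t1") {
  data.frame(gene_a = a, gene_b = b, action_effect = effect,
             confidence_experimental = ce, confidence_database = cd,
             confidence_textmining = ct, location_a = "secreted",
             location_b = "plasma_membrane", terms = terms,
             stringsAsFactors = FALSE)
}

test_that("pair enumeration equals the brute-force cross-join", {
  up_s <- sprintf("L%02d", 1:10); up_r <- sprintf("R%02d", 1:10)
  deg_s <- make_deg(c(up_s, "NsA"), c(rep(1, 10), 0), c(rep(1e-6, 10), 0.9))
  deg_r <- make_deg(c(up_r, "NsB"), c(rep(1, 10), 0), c(rep(1e-6, 10), 0.9))
  db <- do.call(rbind, lapply(up_s, function(a)
    do.call(rbind, lapply(up_r, function(b) db_row(a, b)))))
  pairs <- enumerate_pairs(deg_s, deg_r, db, "up")
  expect_equal(nrow(pairs), 100)
  cross <- expand.grid(gene_a = up_s, gene_b = up_r,
                       stringsAsFactors = FALSE)
  expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                  paste(cross$gene_a, cross$gene_b))
  # deterministic lexicographic order
  expect_identical(order(pairs$gene_a, pairs$gene_b), seq_len(100))
})

test_that("direction filtering and db-gene handling behave as specified", {
  deg_s <- make_deg(c("Ccl3", "Dn1"), c(2, -2), c(1e-8, 1e-8))
  deg_r <- make_deg(c("Ccr5", "Dn2"), c(2, -2), c(1e-8, 1e-8))
  db <- rbind(db_row("Ccl3", "Ccr5"), db_row("Dn1", "Dn2"),
              db_row("Ccl3", "Dn2"))
  expect_equal(nrow(enumerate_pairs(deg_s, deg_r, db, "up")), 1)
  expect_equal(nrow(enumerate_pairs(deg_s, deg_r, db, "down")), 1)
  expect_equal(nrow(enumerate_pairs(deg_s, deg_r, db, "any")), 3)
  # empty DEG tables emit nothing
  empty <- make_deg(character(), numeric(), numeric())
  expect_equal(nrow(suppressWarnings(enumerate_pairs(empty, empty, db, "up"))),
               0)
  # database genes outside the panel warn and are skipped
  expect_warning(
    p <- enumerate_pairs(deg_s, deg_r, rbind(db, db_row("Zzz", "Ccr5")), "up"),
    "absent")
  expect_equal(nrow(p), 1)
})

test_that("power scores follow the two stated conventions", {
  pr <- data.frame(log2fc_a = c(0.5, 1), log2fc_b = c(0.7, -0.2),
                   mean_a = c(2, 0), mean_b = c(1.5, 7))
  expect_equal(score_power(pr, "sum_lfc"), c(1.2, 0.8))
  expect_equal(score_power(pr, "product_expr"), c(3, 0))
})

test_that("confidence aggregation is noisy-OR", {
  expect_equal(combine_confidence(c(0.8, 0.5)), 0.9, tolerance = 1e-12)
  expect_equal(combine_confidence(c(1.0, 0.123)), 1.0)
  expect_equal(combine_confidence(0), 0)
  expect_equal(combine_confidence(0.37), 0.37)
  expect_error(combine_confidence(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing in every channel
  set.seed(3)
  for (i in 1:50) {
    ch <- runif(3)
    j <- sample(3, 1)
    bumped <- ch; bumped[j] <- min(1, ch[j] + runif(1) * (1 - ch[j]))
    expect_gte(combine_confidence(bumped), combine_confidence(ch))
  }
})

test_that("exhaustive permutation matches an independent enumeration", {
  # 4 cells, 2 sender / 2 receiver, gene_a expressed only in sender cells
  m <- rbind(ga = c(3, 2, 0, 0), gb = c(0, 0, 1, 2))
  colnames(m) <- paste0("c", 1:4)
  norm <- make_norm(m)
  labels <- c("s", "s", "r", "r")
  res <- permutation_test(norm, labels, "s", "r", "ga", "gb",
                          exhaustive = TRUE)
  oracle <- brute_perm_p(m["ga", ], m["gb", ], 2, 2, res$t_obs)
  expect_equal(res$n_perm, 6)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(sort(res$t_null), sort(oracle$t_null), tolerance = 1e-12)
})

test_that("constant expression gives a permutation p of exactly 1", {
  m <- rbind(ga = rep(2, 12), gb = rep(0.5, 12))
  colnames(m) <- paste0("c", 1:12)
  labels <- rep(c("s", "r", "x"), each = 4)
  res <- permutation_test(make_norm(m), labels, "s", "r", "ga", "gb",
                          n_perm = 99, seed = 1)
  expect_equal(res$p, 1)
})

test_that("permutation p is reproducible, bounded below, and errors are clear", {
  sim <- small_sim(seed = 19, n = 30)
  norm <- normalize_counts(sim$counts)
  lab <- sim$counts$cell_meta$cluster
  r1 <- permutation_test(norm, lab, "microglia", "tcm", "Ccl3", "Ccr5",
                         n_perm = 50, seed = 4)
  r2 <- permutation_test(norm, lab, "microglia", "tcm", "Ccl3", "Ccr5",
                         n_perm = 50, seed = 4)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 51)
  expect_error(permutation_test(norm, lab, "microglia", "tcm", "NoGene",
                                "Ccr5"), "absent")
  expect_error(permutation_test(norm, lab, "nosuch", "tcm", "Ccl3", "Ccr5"),
               "no cells")
})

test_that("term restriction equals a brute-force filter in both modes", {
  set.seed(23)
  genes <- sprintf("G%02d", 1:30)
  pairs <- data.frame(gene_a = sample(genes, 50, TRUE),
                      gene_b = sample(genes, 50, TRUE),
                      action_effect = sample(c("positive", "negative"),
                                             50, TRUE),
                      stringsAsFactors = FALSE)
  term <- sample(genes, 12)
  both <- term_restrict(pairs, term, "both")
  either <- term_restrict(pairs, term, "either")
  expect_equal(both,
               local({o <- pairs[pairs$gene_a %in% term &
                                   pairs$gene_b %in% term, ]
                      rownames(o) <- NULL; o}))
  expect_equal(either,
               local({o <- pairs[pairs$gene_a %in% term |
                                   pairs$gene_b %in% term, ]
                      rownames(o) <- NULL; o}))
  expect_error(term_restrict(pairs, character(0)), "empty")
  # the all-gene term is the identity
  expect_equal(nrow(term_restrict(pairs, genes, "both")), nrow(pairs))
})

test_that("effect filtering partitions the pair list", {
  pairs <- rbind(db_row("Tnf", "Vcam1", "positive"),
                 db_row("A", "B", "negative"),
                 db_row("C", "D", "unspecified"),
                 db_row("E", "F", "positive"))
  pos <- filter_effect(pairs, "positive")
  expect_equal(nrow(pos), 2)
  expect_true("Tnf" %in% pos$gene_a)
  total <- nrow(filter_effect(pairs, "positive")) +
    nrow(filter_effect(pairs, "negative")) +
    nrow(filter_effect(pairs, "unspecified"))
  expect_equal(total, nrow(pairs))
})

test_that("cell-pair summaries equal a brute-force group-by and conserve rows", {
  set.seed(5)
  types <- sprintf("T%d", 1:5)
  pairs <- data.frame(sender_type = sample(types, 200, TRUE),
                      receiver_type = sample(types, 200, TRUE),
                      log2fc_a = rnorm(200), log2fc_b = rnorm(200),
                      mean_a = runif(200), mean_b = runif(200),
                      stringsAsFactors = FALSE)
  sm <- summarize_cell_pairs(pairs, "sum_lfc")
  expect_equal(sum(sm$n_pairs), 200)
  for (i in seq_len(nrow(sm))) {
    sel <- pairs$sender_type == sm$sender_type[i] &
      pairs$receiver_type == sm$receiver_type[i]
    expect_equal(sm$n_pairs[i], sum(sel))
    expect_equal(sm$total_power[i],
                 sum(pairs$log2fc_a[sel] + pairs$log2fc_b[sel]),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(sm$n_pairs) <= 0))
  # empty input, empty summary; three powers 1,2,3 sum to 6
  expect_equal(nrow(summarize_cell_pairs(pairs[0, ])), 0)
  p3 <- data.frame(sender_type = "a", receiver_type = "b",
                   log2fc_a = c(1, 2, 3), log2fc_b = 0,
                   mean_a = 1, mean_b = 1)
  s3 <- summarize_cell_pairs(p3, "sum_lfc")
  expect_equal(s3$n_pairs, 3L)
  expect_equal(s3$total_power, 6)
})

test_that("crosstalk fit is deterministic and carries planted pairs", {
  sim <- small_sim(seed = 55, n = 60)
  qcd <- qc_filter(sim$counts, qc_params(min_genes = 20))
  norm <- normalize_counts(qcd)
  db <- generate_interaction_db(rownames(sim$counts$counts), seed = 55,
                                n_decoy_pairs = 10)
  fit1 <- crosstalk(norm, qcd$cell_meta$cluster, qcd$cell_meta$age_group,
                    "microglia", "tcm", db, n_perm = 100, seed = 9)
  fit2 <- crosstalk(norm, qcd$cell_meta$cluster, qcd$cell_meta$age_group,
                    "microglia", "tcm", db, n_perm = 100, seed = 9)
  expect_identical(fit1$pairs, fit2$pairs)
  expect_true("Ccl3" %in% fit1$pairs$gene_a)
  expect_true(all(fit1$pairs$perm_p >= 1 / 101))
  expect_equal(fit1$pairs$power_sum,
               fit1$pairs$log2fc_a + fit1$pairs$log2fc_b)
  expect_equal(fit1$pairs$power_product,
               fit1$pairs$mean_a * fit1$pairs$mean_b)
  expect_equal(sum(fit1$summary$n_pairs), nrow(fit1$pairs))
  expect_s3_class(summary(fit1), "summary.crosstalk")
  expect_output(print(fit1), "crosstalk")
})
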