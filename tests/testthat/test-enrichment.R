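# Preranked GSEA, hypergeometric enrichment and activation z-scores.

test_that("ranking metric is sign(lfc) * -log10(p), strictly ordered", {
  deg <- make_deg(c("a", "b", "c"), c(1, -0.5, 2), c(0.01, 0.001, 0.5))
  r <- rank_genes(deg)
  expect_equal(unname(r["a"]), 2, tolerance = 1e-12)
  expect_equal(unname(r["b"]), -3, tolerance = 1e-12)
  expect_identical(names(r), c("a", "c", "b"))
  # identical metric: deterministic name-order tie break
  deg2 <- make_deg(c("zz", "aa"), c(1, 1), c(0.01, 0.01))
  expect_identical(names(rank_genes(deg2)), c("aa", "zz"))
  # permutation property on random tables
  deg3 <- ranked_fixture(100, seed = 13)
  r3 <- rank_genes(deg3)
  expect_setequal(names(r3), deg3$gene)
  expect_true(all(diff(unclass(r3)) <= 1e-12))
  expect_error(rank_genes(make_deg(character(), numeric(), numeric())),
               "empty")
})

test_that("enrichment score equals the step-by-step running-sum oracle", {
  for (seed in c(11, 12, 13)) {
    r <- rank_genes(ranked_fixture(20, seed = seed))
    for (i in 1:40) {
      gs <- sample(names(r), 5)
      es <- gsea_es(r, gs)$es
      expect_equal(es, brute_es(unclass(r), names(r), gs), tolerance = 1e-12)
      expect_gte(es, -1); expect_lte(es, 1)
    }
  }
})

test_that("fast null-path ES agrees with the full running sum", {
  r <- rank_genes(ranked_fixture(60, seed = 21))
  wabs <- abs(unclass(r))
  set.seed(2)
  for (i in 1:60) {
    pos <- sample(60, sample(3:20, 1))
    expect_equal(nichecrosstalk:::es_from_positions(pos, wabs, 60),
                 brute_es(unclass(r), names(r), names(r)[pos]),
                 tolerance = 1e-12)
  }
})

test_that("ES matches an established GSEA implementation", {
  skip_if_not_installed("fgsea")
  r <- rank_genes(ranked_fixture(50, seed = 31))
  set.seed(8)
  for (i in 1:20) {
    gs <- sample(names(r), 8)
    expect_equal(gsea_es(r, gs)$es,
                 fgsea::calcGseaStat(unclass(r), which(names(r) %in% gs),
                                     gseaParam = 1),
                 tolerance = 1e-9)
  }
})

test_that("degenerate gene sets hit the documented limits", {
  r <- rank_genes(ranked_fixture(20, seed = 41))
  expect_equal(gsea_es(r, names(r))$es, 1)           # whole list
  expect_equal(gsea_es(r, names(r)[1])$es, 1)        # single top hit
  expect_error(gsea_es(r, c("nope1", "nope2")), "intersect")
})

test_that("reversing the ranked list flips the sign of ES", {
  r <- rank_genes(ranked_fixture(40, seed = 51))
  rev_r <- structure(rev(unclass(r)), names = rev(names(r)),
                     class = "ranked_list")
  set.seed(9)
  for (i in 1:20) {
    gs <- sample(names(r), 6)
    expect_equal(gsea_es(rev_r, gs)$es, -gsea_es(r, gs)$es,
                 tolerance = 1e-12)
  }
})

test_that("NES/FDR computation is seeded and set-consistent", {
  r <- rank_genes(ranked_fixture(200, seed = 61))
  sets <- list(a = names(r)[1:15], b = sample(names(r), 20),
               a_again = names(r)[1:15])
  g1 <- gsea_nes_fdr(r, sets, n_perm = 200, seed = 3)
  g2 <- gsea_nes_fdr(r, sets, n_perm = 200, seed = 3)
  expect_identical(g1, g2)
  # identical gene sets give identical rows
  expect_equal(g1$es[1], g1$es[3])
  expect_equal(g1$nes[1], g1$nes[3])
  expect_equal(g1$fdr_q[1], g1$fdr_q[3])
  expect_true(all(sign(g1$nes[g1$es != 0]) == sign(g1$es[g1$es != 0])))
  expect_true(all(g1$p_nominal > 0 & g1$p_nominal <= 1))
  expect_true(all(g1$fdr_q >= 0 & g1$fdr_q <= 1))
  expect_error(gsea_nes_fdr(r, sets, n_perm = 0), "n_perm")
})

test_that("hypergeometric enrichment equals closed form and enumeration", {
  # complete 5-of-5 overlap in a background of 20
  expect_equal(term_enrichment(letters[1:5], letters[1:5], 20),
               1 / choose(20, 5), tolerance = 1e-12)
  # disjoint term: upper tail including zero overlap is 1
  expect_equal(term_enrichment(c("a", "b"), c("x", "y", "z"), 20), 1)
  # exhaustive dhyper-sum oracle across all configurations, background <= 30
  for (bg in c(10, 20, 30)) {
    genes <- sprintf("g%02d", seq_len(bg))
    for (t_size in c(1, floor(bg / 3), floor(bg / 2))) {
      for (d_size in c(1, floor(bg / 3), bg - 1)) {
        for (k in 0:min(t_size, d_size)) {
          if (k > d_size || (d_size - k) > (bg - t_size)) next
          term <- genes[seq_len(t_size)]
          deg <- c(genes[seq_len(k)],
                   genes[(t_size + 1):bg][seq_len(d_size - k)])
          expect_equal(term_enrichment(deg, term, bg),
                       brute_hyper_p(k, t_size, d_size, bg),
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(term_enrichment(letters[1:5], letters[1:6], 4), "larger")
})

test_that("hypergeometric p matches one-sided Fisher's exact test", {
  set.seed(77)
  for (i in 1:50) {
    bg <- sample(8:30, 1)
    t_size <- sample(seq_len(bg - 1), 1)
    d_size <- sample(seq_len(bg - 1), 1)
    k <- sample(max(0, t_size + d_size - bg):min(t_size, d_size), 1)
    genes <- sprintf("g%02d", seq_len(bg))
    term <- genes[seq_len(t_size)]
    deg <- c(genes[seq_len(k)],
             setdiff(genes, term)[seq_len(d_size - k)])
    tab <- matrix(c(k, t_size - k, d_size - k,
                    bg - t_size - d_size + k), nrow = 2)
    expect_equal(term_enrichment(deg, term, bg),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("activation z-score matches its formula over the full grid", {
  for (n_up in c(0, 1, 2, 4, 10, 25, 50)) {
    for (n_down in c(0, 1, 3, 10, 50)) {
      n <- n_up + n_down
      genes <- sprintf("g%03d", seq_len(max(n, 1)))
      deg <- make_deg(genes,
                      log2fc = c(rep(1, n_up), rep(-1, n_down),
                                 rep(0, max(n, 1) - n)),
                      p_raw = 1e-10,
                      direction = c(rep("up", n_up), rep("down", n_down),
                                    rep("ns", max(n, 1) - n)))
      z <- activation_z(genes, deg, background_size = 1000)
      if (n == 0) {
        expect_true(is.na(z$z))
        expect_false(z$significant)
      } else {
        expect_equal(z$z, (n_up - n_down) / sqrt(n), tolerance = 1e-12)
        expect_equal(z$n_annotated_degs, n)
      }
    }
  }
  # spot values: 4 up / 0 down -> 2; 1 up -> 1; balanced -> 0
  d4 <- make_deg(sprintf("u%d", 1:4), rep(2, 4), rep(1e-9, 4))
  expect_equal(activation_z(d4$gene, d4, 100)$z, 2)
  d1 <- make_deg("u1", 2, 1e-9)
  expect_equal(activation_z(d1$gene, d1, 100)$z, 1)
  db <- make_deg(c("u1", "d1"), c(2, -2), c(1e-9, 1e-9))
  expect_equal(activation_z(db$gene, db, 100)$z, 0)
})
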