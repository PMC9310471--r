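# Synthetic data generator: seeded negative-binomial scRNA-seq counts with
# planted aged-niche signals, an annotated gene-pair database, and gene-set
# collections. Ground truth is emitted alongside the data so every downstream
# stage can be tested against known answers.

MT_GENES <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Atp8", "Atp6", "Co3",
                            "Nd3", "Nd4l", "Nd4", "Nd5", "Nd6", "Cytb"))

# Signal genes and the cell types in which they are expressed at baseline.
# Chemokines/cytokines sit in microglia, their receptors and integrins in
# memory T cells, adhesion molecules and TNF receptor in venous endothelium,
# tight-junction genes in capillary endothelium.
signal_gene_table <- function() {
  data.frame(
    gene = c("Ccl3", "Ccl4", "Tnf", "Spp1",
             "Ccr1", "Ccr2", "Ccr5", "Itgb1", "Itgb2", "Sell", "Cd44",
             "Vcam1", "Icam1", "Tnfrsf1a",
             "Cldn5", "Ocln"),
    home = c("microglia", "microglia", "microglia", "microglia",
             "tcm", "tcm", "tcm", "tcm", "tcm", "tcm", "tcm",
             "bec_venous", "bec_venous", "bec_venous",
             "bec_capillary", "bec_capillary"),
    base = c(2, 2, 2, 2,
             2, 2, 2, 2, 2, 3, 3,
             2, 2, 2,
             4, 4),
    stringsAsFactors = FALSE
  )
}

default_planted_effects <- function(fold = 4) {
  data.frame(
    gene = c("Ccl3", "Ccl4", "Tnf", "Spp1",
             "Ccr2", "Ccr5", "Itgb1", "Itgb2",
             "Vcam1", "Icam1",
             "Cldn5", "Ocln"),
    cell_type = c(rep("microglia", 4), rep("tcm", 4),
                  rep("bec_venous", 2), rep("bec_capillary", 2)),
    age_group = "old",
    fold_change = c(rep(fold, 10), 0.25, 0.25),
    stringsAsFactors = FALSE
  )
}

default_planted_pairs <- function() {
  data.frame(
    sender_type = c(rep("microglia", 4), rep("bec_venous", 3),
                    "microglia", "microglia", "microglia"),
    gene_a = c("Ccl3", "Ccl3", "Ccl4", "Tnf",
               "Vcam1", "Vcam1", "Icam1",
               "Tnf", "Tnf", "Spp1"),
    receiver_type = c(rep("tcm", 4), rep("tcm", 3),
                      rep("bec_venous", 3)),
    gene_b = c("Ccr5", "Ccr1", "Ccr5", "Tnfrsf1a",
               "Itgb1", "Itgb2", "Itgb2",
               "Vcam1", "Icam1", "Icam1"),
    action_effect = c(rep("unspecified", 4), rep("positive", 3),
                      "positive", "positive", "positive"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for the synthetic aged-niche dataset
#'
#' Builds the full parameter set for [generate_counts()]: the cell-type
#' panel, gene panel (signal genes, per-type marker blocks, mitochondrial
#' genes, background genes), per-gene/per-type negative-binomial base means,
#' dispersions, planted fold changes, library-size factor distribution, and
#' the number of QC decoy cells.
#'
#' Defaults emulate an aged-brain immune niche: two age groups (`young`,
#' `old`), seven cell types (microglia, central/effector memory CD8 T cells,
#' macrophages, arterial/capillary/venous endothelium) with 300 cells per
#' type per age group, and fold-4 planted up-regulation of Ccl3/Ccl4/Tnf/Spp1
#' in aged microglia, Ccr2/Ccr5/Itgb1/Itgb2 in aged central-memory T cells
#' and Vcam1/Icam1 in aged venous endothelium, plus fold-0.25 down-regulation
#' of Cldn5/Ocln in aged capillary endothelium. The gene panel exceeds the
#' upper QC detection bound (2500 genes) so that over-detection decoy cells
#' are constructible.
#'
#' @param cell_types named integer vector: cells per age group for each type.
#' @param n_background_genes number of unstructured background genes.
#' @param planted_effects data.frame (`gene`, `cell_type`, `age_group`,
#'   `fold_change`); `fold_change = 0` models a knockout.
#' @param planted_pairs data.frame of ground-truth interacting pairs
#'   (`sender_type`, `gene_a`, `receiver_type`, `gene_b`, `action_effect`).
#' @param base_mean_background meanlog/sdlog-free scalar location for
#'   background gene NB means (drawn lognormal around it, seeded).
#' @param nb_dispersion NB dispersion theta (variance `mu + mu^2/theta`);
#'   scalar or per-gene named vector.
#' @param lib_sdlog sdlog of the lognormal(0, `lib_sdlog`) library-size
#'   factor.
#' @param qc_decoys list with counts of decoy cells: `low_genes` (detected
#'   genes forced below 200), `high_genes` (above 2500), `high_mito`
#'   (mitochondrial fraction forced above 0.10).
#' @param n_markers_per_type marker genes per cell type (drive clustering).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(cell_types = c(microglia = 300, tcm = 300, tem = 300,
                                      macrophage = 300, bec_arterial = 300,
                                      bec_capillary = 300, bec_venous = 300),
                       n_background_genes = 2800,
                       planted_effects = default_planted_effects(),
                       planted_pairs = default_planted_pairs(),
                       base_mean_background = 0.25,
                       nb_dispersion = 2,
                       lib_sdlog = 0.3,
                       qc_decoys = list(low_genes = 10, high_genes = 10,
                                        high_mito = 10),
                       n_markers_per_type = 20,
                       seed = 1L) {
  stopifnot(is.numeric(cell_types), !is.null(names(cell_types)),
            all(cell_types >= 1))
  types <- names(cell_types)
  sig <- signal_gene_table()

  # the default truth tables cover the full seven-type niche; when a reduced
  # panel is simulated, restrict them to the types present
  if (missing(planted_effects))
    planted_effects <- planted_effects[planted_effects$cell_type %in% types, ,
                                       drop = FALSE]
  if (missing(planted_pairs))
    planted_pairs <- planted_pairs[planted_pairs$sender_type %in% types &
                                     planted_pairs$receiver_type %in% types, ,
                                   drop = FALSE]

  markers <- unlist(lapply(types, function(ty)
    sprintf("Mk_%s_%02d", ty, seq_len(n_markers_per_type))))
  background <- sprintf("Gene%04d", seq_len(n_background_genes))
  panel <- unique(c(sig$gene, markers, MT_GENES, background))

  # per-gene x per-type base means (seeded, part of the config itself)
  base <- with_seed(derive_seed(seed, "base_mean"), {
    m <- matrix(rlnorm(length(panel) * length(types),
                       meanlog = log(base_mean_background), sdlog = 0.6),
                nrow = length(panel), ncol = length(types),
                dimnames = list(panel, types))
    for (i in seq_len(nrow(sig))) {          # signal genes: home-type baseline
      m[sig$gene[i], ] <- 0.1
      if (sig$home[i] %in% types) m[sig$gene[i], sig$home[i]] <- sig$base[i]
      # tight-junction genes are expressed across the endothelium
      if (sig$gene[i] %in% c("Cldn5", "Ocln"))
        m[sig$gene[i], grep("^bec_", types, value = TRUE)] <- sig$base[i] / 2
    }
    if ("Cldn5" %in% panel && "bec_capillary" %in% types)
      m["Cldn5", "bec_capillary"] <- 4
    if ("Ocln" %in% panel && "bec_capillary" %in% types)
      m["Ocln", "bec_capillary"] <- 4
    for (ty in types) {                      # disjoint marker blocks
      mk <- sprintf("Mk_%s_%02d", ty, seq_len(n_markers_per_type))
      m[mk, ] <- 0.02
      m[mk, ty] <- 3
    }
    # mitochondrial load ~4% of each type's total expression
    non_mt <- setdiff(panel, MT_GENES)
    for (ty in types)
      m[MT_GENES, ty] <- 0.0435 * sum(m[non_mt, ty]) / length(MT_GENES)
    m
  })

  disp <- if (length(nb_dispersion) == 1L)
    setNames(rep(nb_dispersion, length(panel)), panel) else nb_dispersion

  cfg <- structure(list(
    cell_types = cell_types,
    age_groups = c("young", "old"),
    gene_panel = panel,
    mito_genes = MT_GENES,
    base_mean = base,
    nb_dispersion = disp,
    planted_effects = planted_effects,
    planted_pairs = planted_pairs,
    lib_sdlog = lib_sdlog,
    qc_decoys = qc_decoys,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pe <- cfg$planted_effects
  if (nrow(pe)) {
    bad <- setdiff(pe$gene, cfg$gene_panel)
    if (length(bad))
      stopf("planted effect gene(s) not in panel: %s", paste(bad, collapse = ", "))
    bad <- setdiff(pe$cell_type, names(cfg$cell_types))
    if (length(bad))
      stopf("planted effect cell type(s) unknown: %s", paste(bad, collapse = ", "))
    bad <- setdiff(pe$age_group, cfg$age_groups)
    if (length(bad))
      stopf("planted effect age group(s) unknown: %s", paste(bad, collapse = ", "))
    if (any(pe$fold_change < 0))
      stopf("fold_change must be >= 0")
  }
  if (any(cfg$nb_dispersion <= 0))
    stopf("nb_dispersion must be positive")
  invisible(cfg)
}

#' Simulate a count matrix with planted ground truth
#'
#' Draws `counts[g, c] ~ NB(mean = base_mean[g, type(c)] * fold(g, type, age)
#' * lib_factor[c], dispersion = theta[g])` independently, appends QC decoy
#' cells whose detected-gene counts fall outside `[200, 2500]` or whose
#' mitochondrial fraction exceeds 0.10, and returns the counts together with
#' a truth table of planted effects, planted interacting pairs and decoy
#' cell ids.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_matrix]; `cell_meta` gains a
#'   logical `decoy` column) and `truth` (list: `effects`, `pairs`,
#'   `decoy_cells`).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  types <- names(config$cell_types)
  genes <- config$gene_panel
  ng <- length(genes)
  qd <- config$qc_decoys
  n_decoy <- sum(unlist(qd))
  if ((qd$high_genes %||% 0) > 0 && ng <= 2550)
    stopf("gene panel too small (%d) to construct over-detection decoys", ng)

  fold_for <- function(type, age) {
    f <- setNames(rep(1, ng), genes)
    pe <- config$planted_effects
    sel <- pe$cell_type == type & pe$age_group == age
    if (any(sel)) f[pe$gene[sel]] <- pe$fold_change[sel]
    f
  }

  with_seed(derive_seed(config$seed, "counts"), {
    blocks <- list(); meta <- list()
    for (ty in types) for (age in config$age_groups) {
      n <- config$cell_types[[ty]]
      lib <- rlnorm(n, 0, config$lib_sdlog)
      mu <- (config$base_mean[, ty] * fold_for(ty, age)) %o% lib
      cnt <- matrix(rnbinom(ng * n, mu = mu,
                            size = rep(config$nb_dispersion, n)),
                    nrow = ng)
      ids <- sprintf("%s_%s_%03d", ty, age, seq_len(n))
      colnames(cnt) <- ids
      blocks[[paste(ty, age)]] <- cnt
      meta[[paste(ty, age)]] <- data.frame(
        cell_id = ids, cluster = ty, age_group = age,
        sample_id = sprintf("%s_%d", age, (seq_len(n) - 1L) %% 3L + 1L),
        decoy = FALSE, stringsAsFactors = FALSE)
    }

    # decoy cells: simulated as ordinary cells of rotating types, then broken
    decoy_kinds <- rep(c("low_genes", "high_genes", "high_mito"),
                       c(qd$low_genes %||% 0, qd$high_genes %||% 0,
                         qd$high_mito %||% 0))
    if (length(decoy_kinds)) {
      dty <- types[(seq_along(decoy_kinds) - 1L) %% length(types) + 1L]
      dage <- config$age_groups[(seq_along(decoy_kinds) - 1L) %% 2L + 1L]
      dmat <- matrix(0L, nrow = ng, ncol = length(decoy_kinds))
      for (j in seq_along(decoy_kinds)) {
        mu <- config$base_mean[, dty[j]] * fold_for(dty[j], dage[j]) *
          rlnorm(1, 0, config$lib_sdlog)
        v <- rnbinom(ng, mu = mu, size = config$nb_dispersion)
        if (decoy_kinds[j] == "low_genes") {
          keep <- sample(which(v > 0), min(150L, sum(v > 0)))
          w <- integer(ng); w[keep] <- v[keep]
          if (sum(w) == 0) w[sample.int(ng, 1)] <- 1L
          v <- w
        } else if (decoy_kinds[j] == "high_genes") {
          zero <- which(v == 0)
          need <- 2600L - sum(v > 0)
          v[sample(zero, min(need, length(zero)))] <- 1L
        } else {                                   # high_mito
          tot <- sum(v[!(genes %in% config$mito_genes)])
          v[match(config$mito_genes, genes)] <-
            as.integer(ceiling(0.25 * max(tot, 100) / length(config$mito_genes)))
        }
        dmat[, j] <- v
      }
      ids <- sprintf("decoy_%03d", seq_along(decoy_kinds))
      colnames(dmat) <- ids
      blocks[["decoys"]] <- dmat
      meta[["decoys"]] <- data.frame(
        cell_id = ids, cluster = dty, age_group = dage,
        sample_id = paste0(dage, "_1"), decoy = TRUE,
        stringsAsFactors = FALSE)
    }

    counts <- do.call(cbind, blocks)
    rownames(counts) <- genes
    cm <- count_matrix(counts, do.call(rbind, c(meta, make.row.names = FALSE)))
    truth <- list(effects = config$planted_effects,
                  pairs = config$planted_pairs,
                  decoy_cells = if (length(decoy_kinds))
                    data.frame(cell_id = meta[["decoys"]]$cell_id,
                               kind = decoy_kinds,
                               stringsAsFactors = FALSE)
                  else data.frame(cell_id = character(), kind = character()))
    list(counts = cm, truth = truth)
  })
}

#' Generate an annotated gene-pair interaction database
#'
#' Produces a directed ligand-receptor reference: all planted pairs plus
#' `n_decoy_pairs` unique decoy pairs drawn from panel genes that take part
#' in no planted pair. Each record carries an action effect, three evidence
#' -channel confidences in `[0, 1]`, subcellular locations for both members
#' and at least one functional-term annotation.
#'
#' @param gene_panel character vector of valid gene symbols.
#' @param planted_pairs data.frame with `gene_a`, `gene_b` and optionally
#'   `action_effect`; defaults to the aged-niche truth pairs.
#' @param n_decoy_pairs number of decoy records to add.
#' @param seed integer seed; identical seeds give identical databases.
#' @return data.frame of class `interaction_db` with columns `gene_a`,
#'   `gene_b`, `action_effect`, `confidence_experimental`,
#'   `confidence_database`, `confidence_textmining`, `location_a`,
#'   `location_b`, `terms` (semicolon-separated term ids).
#' @export
generate_interaction_db <- function(gene_panel,
                                    planted_pairs = default_planted_pairs(),
                                    n_decoy_pairs = 40, seed = 1L) {
  pp <- unique(planted_pairs[, intersect(c("gene_a", "gene_b", "action_effect"),
                                         names(planted_pairs)), drop = FALSE])
  bad <- setdiff(c(pp$gene_a, pp$gene_b), gene_panel)
  if (length(bad))
    stopf("planted pair gene(s) not in panel: %s", paste(bad, collapse = ", "))
  if (is.null(pp$action_effect))
    pp$action_effect <- rep("unspecified", nrow(pp))

  secreted <- c("Ccl3", "Ccl4", "Tnf", "Spp1")
  migration <- c("Vcam1", "Icam1", "Itgb1", "Itgb2", "Sell",
                 "Ccr2", "Ccr5", "Ccr1", "Ccl3", "Ccl4")
  term_for <- function(a, b) {
    t <- "immunoregulatory_interactions"
    if (a %in% migration || b %in% migration)
      t <- paste(t, "leukocyte_migration", sep = ";")
    if (a %in% secreted) t <- paste(t, "cytokine_signaling", sep = ";")
    t
  }

  with_seed(derive_seed(seed, "interaction_db"), {
    n_p <- nrow(pp)
    planted <- if (n_p) data.frame(
      gene_a = pp$gene_a, gene_b = pp$gene_b,
      action_effect = pp$action_effect,
      confidence_experimental = round(runif(n_p, 0.6, 0.95), 3),
      confidence_database = round(runif(n_p, 0.4, 0.9), 3),
      confidence_textmining = round(runif(n_p, 0.2, 0.8), 3),
      location_a = ifelse(pp$gene_a %in% secreted, "secreted",
                          "plasma_membrane"),
      location_b = "plasma_membrane",
      terms = mapply(term_for, pp$gene_a, pp$gene_b, USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    else NULL

    decoys <- NULL
    if (n_decoy_pairs > 0) {
      free <- setdiff(gene_panel, c(pp$gene_a, pp$gene_b))
      if (length(free) < 2)
        stopf("not enough non-planted genes to draw decoy pairs")
      avail <- length(free) * (length(free) - 1L)
      if (n_decoy_pairs > avail)
        stopf("requested %d decoy pairs but only %d ordered pairs available",
              n_decoy_pairs, avail)
      seen <- character(0); ga <- gb <- character(n_decoy_pairs); k <- 0L
      while (k < n_decoy_pairs) {
        cand <- sample(free, 2)
        key <- paste(cand, collapse = "\r")
        if (key %in% seen) next
        seen <- c(seen, key); k <- k + 1L
        ga[k] <- cand[1]; gb[k] <- cand[2]
      }
      decoys <- data.frame(
        gene_a = ga, gene_b = gb,
        action_effect = sample(c("positive", "negative", "unspecified"),
                               n_decoy_pairs, replace = TRUE),
        confidence_experimental = round(runif(n_decoy_pairs, 0.1, 0.9), 3),
        confidence_database = round(runif(n_decoy_pairs, 0.1, 0.9), 3),
        confidence_textmining = round(runif(n_decoy_pairs, 0.1, 0.9), 3),
        location_a = sample(c("secreted", "plasma_membrane", "intracellular",
                              "other"), n_decoy_pairs, replace = TRUE),
        location_b = sample(c("plasma_membrane", "intracellular", "other"),
                            n_decoy_pairs, replace = TRUE),
        terms = "background_process",
        stringsAsFactors = FALSE)
    }
    db <- rbind(planted, decoys)
    db <- db[!duplicated(db[, c("gene_a", "gene_b")]), , drop = FALSE]
    rownames(db) <- NULL
    class(db) <- c("interaction_db", "data.frame")
    db
  })
}

#' Generate a gene-set collection
#'
#' Random decoy sets drawn from the panel plus any planted sets supplied
#' verbatim (e.g. a set concentrated among planted up-regulated genes, for
#' GSEA power checks).
#'
#' @param gene_panel character vector to draw from.
#' @param n_sets number of random sets.
#' @param size_range inclusive bounds on random set sizes.
#' @param planted_sets named list of character vectors prepended verbatim.
#' @param seed integer seed.
#' @return named list of character vectors (a gene-set collection).
#' @export
generate_gene_sets <- function(gene_panel, n_sets = 20,
                               size_range = c(10, 50),
                               planted_sets = list(), seed = 1L) {
  with_seed(derive_seed(seed, "gene_sets"), {
    rand <- lapply(seq_len(n_sets), function(i)
      sample(gene_panel, sample(size_range[1]:size_range[2], 1)))
    names(rand) <- sprintf("random_set_%02d", seq_len(n_sets))
    c(planted_sets, rand)
  })
}

#' Default functional-term gene sets for the aged-niche simulation
#'
#' Two biology-anchored terms used throughout: `leukocyte_migration`
#' (adhesion molecules, integrins, selectins, chemokine receptors) and
#' `inflammatory_response` (chemokines, cytokines and their receptors).
#'
#' @return named list of character vectors.
#' @export
default_term_sets <- function() {
  list(
    leukocyte_migration = c("Vcam1", "Icam1", "Itgb1", "Itgb2", "Sell",
                            "Ccr2", "Ccr5", "Ccr1", "Ccl3", "Ccl4"),
    inflammatory_response = c("Ccl3", "Ccl4", "Tnf", "Spp1", "Tnfrsf1a",
                              "Ccr1", "Ccr2", "Ccr5")
  )
}
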