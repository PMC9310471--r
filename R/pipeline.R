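# End-to-end orchestration: simulate (or load) -> QC -> normalize -> DE ->
# interaction -> enrichment, with per-stage seeds derived from one global
# seed, commented-TSV outputs and a manifest of md5 hashes for regression
# detection.

#' Build or read a pipeline run configuration
#'
#' With no file paths the pipeline simulates its inputs. Paths given must
#' exist at validation time.
#'
#' @param counts_dir directory holding `matrix.mtx` / `genes.tsv` /
#'   `cell_meta.tsv`, or `NULL` to simulate.
#' @param db_path interaction-database TSV, or `NULL` to generate.
#' @param gmt_path GMT gene-set file, or `NULL` to generate.
#' @param qc list overriding [qc_params()] fields.
#' @param contrast list: `sender_type`, `receiver_type`, `mode`
#'   (`"age"`/`"marker"`), `age_a`, `age_b`.
#' @param interact list: `direction_filter`, `power_mode`, `term` (term id
#'   resolved in the GMT, or `NULL`), `term_mode`, `effect`, `n_perm`.
#' @param enrich list: `n_perm`.
#' @param sim a [sim_config()] used when `counts_dir` is `NULL` (built with
#'   defaults and the run seed otherwise).
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts_dir = NULL, db_path = NULL, gmt_path = NULL,
                       qc = list(), contrast = list(), interact = list(),
                       enrich = list(), sim = NULL, seed = 1L,
                       out_dir = tempfile("nichecrosstalk_run_")) {
  cfg <- structure(list(
    counts_dir = counts_dir, db_path = db_path, gmt_path = gmt_path,
    qc = utils::modifyList(list(min_genes = 200, max_genes = 2500,
                                max_mito_fraction = 0.10), qc),
    contrast = utils::modifyList(list(sender_type = "microglia",
                                      receiver_type = "tcm",
                                      mode = "age", age_a = "old",
                                      age_b = "young"), contrast),
    interact = utils::modifyList(list(direction_filter = "up",
                                      power_mode = "sum_lfc",
                                      term = NULL, term_mode = "both",
                                      effect = NULL, n_perm = 1000),
                                 interact),
    enrich = utils::modifyList(list(n_perm = 1000), enrich),
    sim = sim, seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param path YAML file with the fields above.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

validate_run_config <- function(cfg) {
  for (p in c("counts_dir", "db_path", "gmt_path")) {
    v <- cfg[[p]]
    if (!is.null(v) && !file.exists(v))
      stopf("config %s does not exist: %s", p, v)
  }
  if (!cfg$contrast$mode %in% c("age", "marker"))
    stopf("contrast mode must be 'age' or 'marker'")
  invisible(cfg)
}

# Small deterministic digest of the config for output headers.
config_digest <- function(cfg) {
  sprintf("%08x", str_hash31(paste(deparse(cfg[setdiff(names(cfg), "out_dir")]),
                                   collapse = "")))
}

#' Run the full crosstalk pipeline
#'
#' Executes simulate/load -> QC -> normalize -> DE -> interaction ->
#' enrichment, writing every intermediate table as a commented TSV under
#' `config$out_dir` plus a `manifest.tsv` (stage, output, md5, seed,
#' seconds). Re-running with an identical configuration reproduces identical
#' table contents, which the manifest hashes certify.
#'
#' @param config a [run_config()].
#' @return list (invisibly): the fitted [crosstalk] object, the DEG tables,
#'   GSEA and z-score tables, the manifest, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  manifest <- list()
  note <- function(stage, path, seed, t0) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, output = basename(path),
      md5 = unname(tools::md5sum(path)), seed = seed,
      seconds = round(as.numeric(Sys.time()) - t0, 3),
      stringsAsFactors = FALSE)
  }
  hdr <- function(seed) c(package = "nichecrosstalk", seed = seed,
                          config = digest)
  stage_log <- function(s) message(sprintf("[nichecrosstalk] stage: %s", s))

  # -- inputs ---------------------------------------------------------------
  t0 <- as.numeric(Sys.time()); stage_log("inputs")
  seed_sim <- derive_seed(config$seed, "simulate")
  if (is.null(config$counts_dir)) {
    sim_cfg <- config$sim %||% sim_config(seed = seed_sim)
    sim <- generate_counts(sim_cfg)
    counts <- sim$counts
    sim_dir <- file.path(config$out_dir, "sim")
    write_counts_mtx(counts, sim_dir)
    note("simulate", file.path(sim_dir, "matrix.mtx"), seed_sim, t0)
  } else {
    counts <- read_counts_mtx(config$counts_dir)
    sim <- NULL
  }
  db <- if (is.null(config$db_path)) {
    d <- generate_interaction_db(rownames(counts$counts),
                                 seed = derive_seed(config$seed, "db"))
    write_interaction_db(d, file.path(config$out_dir, "interaction_db.tsv"))
    d
  } else read_interaction_db(config$db_path)
  sets <- if (is.null(config$gmt_path)) {
    s <- c(default_term_sets(),
           generate_gene_sets(rownames(counts$counts), n_sets = 10,
                              seed = derive_seed(config$seed, "sets")))
    write_gmt(s, file.path(config$out_dir, "gene_sets.gmt"))
    s
  } else read_gmt(config$gmt_path)

  # -- qc + normalize -------------------------------------------------------
  t0 <- as.numeric(Sys.time()); stage_log("qc")
  qcp <- qc_params(config$qc$min_genes, config$qc$max_genes,
                   config$qc$max_mito_fraction)
  filtered <- qc_filter(counts, qcp)
  write_tsv_commented(filtered$cell_meta,
                      file.path(config$out_dir, "cells_passing_qc.tsv"),
                      hdr(config$seed))
  note("qc", file.path(config$out_dir, "cells_passing_qc.tsv"),
       config$seed, t0)
  norm <- normalize_counts(filtered)

  # -- crosstalk fit (includes both DE tables and permutation tests) --------
  t0 <- as.numeric(Sys.time()); stage_log("interact")
  ct <- config$contrast; it <- config$interact
  term_genes <- if (!is.null(it$term)) {
    if (!it$term %in% names(sets)) stopf("term %s not in gene sets", it$term)
    sets[[it$term]]
  } else NULL
  seed_int <- derive_seed(config$seed, "interact")
  fit <- crosstalk(norm, filtered$cell_meta$cluster,
                   filtered$cell_meta$age_group,
                   ct$sender_type, ct$receiver_type, db,
                   contrast = ct$mode, age_a = ct$age_a, age_b = ct$age_b,
                   direction_filter = it$direction_filter,
                   power_mode = it$power_mode,
                   term = term_genes, term_mode = it$term_mode,
                   effect = it$effect, n_perm = it$n_perm, seed = seed_int)
  for (nm in c("deg_sender", "deg_receiver")) {
    f <- file.path(config$out_dir, paste0(nm, ".tsv"))
    write_tsv_commented(fit[[nm]], f, hdr(seed_int))
    note("deg", f, seed_int, t0)
  }
  write_tsv_commented(fit$pairs, file.path(config$out_dir, "pairs.tsv"),
                      hdr(seed_int))
  note("interact", file.path(config$out_dir, "pairs.tsv"), seed_int, t0)
  write_tsv_commented(fit$summary,
                      file.path(config$out_dir, "cell_pair_summary.tsv"),
                      hdr(seed_int))
  note("interact", file.path(config$out_dir, "cell_pair_summary.tsv"),
       seed_int, t0)
  flows <- fit$summary[, c("sender_type", "receiver_type", "n_pairs")]
  names(flows) <- c("source", "target", "value")
  write_tsv_commented(flows, file.path(config$out_dir, "flows.tsv"),
                      hdr(seed_int))
  note("interact", file.path(config$out_dir, "flows.tsv"), seed_int, t0)

  # -- enrichment -----------------------------------------------------------
  t0 <- as.numeric(Sys.time()); stage_log("enrich")
  seed_enr <- derive_seed(config$seed, "enrich")
  ranked <- rank_genes(fit$deg_sender)
  usable <- sets[vapply(sets, function(s)
    length(intersect(s, names(ranked))) > 0, TRUE)]
  gsea <- gsea_nes_fdr(ranked, usable, n_perm = config$enrich$n_perm,
                       seed = seed_enr)
  write_tsv_commented(gsea, file.path(config$out_dir, "gsea_results.tsv"),
                      hdr(seed_enr))
  note("enrich", file.path(config$out_dir, "gsea_results.tsv"), seed_enr, t0)
  zs <- do.call(rbind, lapply(names(usable), function(nm) {
    z <- activation_z(usable[[nm]], fit$deg_sender,
                      background_size = length(counts$counts@Dimnames[[1]]))
    cbind(data.frame(term = nm, stringsAsFactors = FALSE), z)
  }))
  write_tsv_commented(zs, file.path(config$out_dir, "go_zscores.tsv"),
                      hdr(seed_enr))
  note("enrich", file.path(config$out_dir, "go_zscores.tsv"), seed_enr, t0)

  manifest <- do.call(rbind, manifest)
  write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fit = fit, deg_sender = fit$deg_sender,
                 deg_receiver = fit$deg_receiver, gsea = gsea, zscores = zs,
                 manifest = manifest, truth = if (!is.null(sim)) sim$truth,
                 out_dir = config$out_dir))
}
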