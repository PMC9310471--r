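# Fixture formats: Matrix Market counts with TSV sidecars, the gene-pair
# database TSV, and GMT gene-set collections. All readers validate enough of
# the format to fail with a line number rather than a downstream surprise.

DB_COLUMNS <- c("gene_a", "gene_b", "action_effect",
                "confidence_experimental", "confidence_database",
                "confidence_textmining", "location_a", "location_b", "terms")

#' Write / read a count matrix as Matrix Market plus TSV sidecars
#'
#' `write_counts_mtx()` writes `matrix.mtx` (sparse coordinate format, genes
#' as rows), `genes.tsv` (one gene per line) and `cell_meta.tsv` (cell id
#' plus metadata). `read_counts_mtx()` reads them back; the round trip is an
#' identity.
#'
#' @param x a [count_matrix].
#' @param dir directory to write into (created if missing).
#' @return `write_counts_mtx()` the directory, invisibly;
#'   `read_counts_mtx()` a [count_matrix].
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stopf("no matrix.mtx under %s", dir)
  hdr <- readLines(mtx, n = 1L)
  if (!grepl("^%%MatrixMarket[ \t]+matrix[ \t]+coordinate", hdr))
    stopf("parse error in %s line 1: not a Matrix Market coordinate header", mtx)
  m <- methods::as(methods::as(Matrix::readMM(mtx), "generalMatrix"),
                   "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  if (length(genes) != nrow(m))
    stopf("genes.tsv has %d lines but matrix has %d rows", length(genes), nrow(m))
  meta <- read_checked_tsv(file.path(dir, "cell_meta.tsv"))
  if (nrow(meta) != ncol(m))
    stopf("cell_meta.tsv has %d rows but matrix has %d columns",
          nrow(meta), ncol(m))
  dimnames(m) <- list(genes, meta$cell_id)
  if ("decoy" %in% names(meta)) meta$decoy <- as.logical(meta$decoy)
  count_matrix(m, meta)
}

# TSV reader that rejects ragged rows with the offending line number.
read_checked_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stopf("parse error in %s line 1: empty file", path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != nf[1])
  if (length(bad))
    stopf("parse error in %s line %d: expected %d fields, found %d",
          path, bad[1], nf[1], nf[bad[1]])
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read the gene-pair interaction database TSV
#'
#' Nine tab-separated columns: `gene_a`, `gene_b`, `action_effect`, the three
#' per-channel confidences, both subcellular locations, and a
#' semicolon-separated `terms` field.
#'
#' @param db an `interaction_db` data.frame (see
#'   [generate_interaction_db()]).
#' @param path file path.
#' @return `read_interaction_db()` an `interaction_db` data.frame.
#' @export
write_interaction_db <- function(db, path) {
  stopifnot(all(DB_COLUMNS %in% names(db)))
  write.table(db[, DB_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_interaction_db
#' @export
read_interaction_db <- function(path) {
  db <- read_checked_tsv(path)
  miss <- setdiff(DB_COLUMNS, names(db))
  if (length(miss))
    stopf("interaction DB %s missing column(s): %s", path,
          paste(miss, collapse = ", "))
  conf <- grep("^confidence_", DB_COLUMNS, value = TRUE)
  for (cc in conf)
    if (any(db[[cc]] < 0 | db[[cc]] > 1))
      stopf("interaction DB %s: %s outside [0, 1]", path, cc)
  if (anyDuplicated(db[, c("gene_a", "gene_b")]))
    stopf("interaction DB %s: duplicate (gene_a, gene_b) records", path)
  class(db) <- c("interaction_db", "data.frame")
  db
}

#' Write / read gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' An empty collection is a valid zero-line file.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @return `read_gmt()` a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stopf("parse error in %s line %d: GMT lines need >= 3 fields", path, bad[1])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

# TSV with a commented header block (seed, config digest) used by the
# pipeline so every table records its provenance yet stays machine-readable.
write_tsv_commented <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in names(header))
    writeLines(sprintf("# %s: %s", h, header[[h]]), con)
  flat <- df
  for (j in seq_along(flat))
    if (is.list(flat[[j]]))
      flat[[j]] <- vapply(flat[[j]], paste, "", collapse = ";")
  suppressWarnings(write.table(flat, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

read_tsv_commented <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
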