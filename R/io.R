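# Plumbing for the on-disk exchange formats: Matrix Market sparse counts
# with TSV sidecars for genes and cell metadata, and headered TSV tables
# for TPM matrices, cohorts and result tables. All text is UTF-8 and
# tab-delimited.

#' Write an ExpressionAtlas to disk
#'
#' Writes `<prefix>_counts.mtx` (Matrix Market coordinate format, 1-based
#' indices, cells as rows), `<prefix>_genes.tsv` and `<prefix>_cells.tsv`.
#'
#' @param atlas An [expression_atlas()] object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"atlas"`.
#' @return Invisibly, the paths written.
#' @export
write_atlas <- function(atlas, dir, prefix = "atlas") {
  assert_that(inherits(atlas, "ExpressionAtlas"), "atlas must be an ExpressionAtlas")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_counts.mtx", "_genes.tsv", "_cells.tsv")))
  Matrix::writeMM(atlas$counts, paths[1])
  write_tsv(data.frame(gene_id = atlas$gene_ids), paths[2])
  write_tsv(atlas$cell_meta, paths[3])
  invisible(paths)
}

#' Read an ExpressionAtlas written by [write_atlas()]
#'
#' @param dir Directory holding the three files.
#' @param prefix File-name prefix used when writing.
#' @return An `ExpressionAtlas`.
#' @export
read_atlas <- function(dir, prefix = "atlas") {
  paths <- file.path(dir, paste0(prefix, c("_counts.mtx", "_genes.tsv", "_cells.tsv")))
  for (pth in paths) assert_that(file.exists(pth), sprintf("missing file: %s", pth))
  counts <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  genes <- read_tsv(paths[2])
  cells <- read_tsv(paths[3])
  expression_atlas(counts, gene_ids = genes$gene_id, cell_meta = cells)
}

#' Tab-separated table helpers
#'
#' Thin wrappers enforcing the package's TSV conventions: header row,
#' tab-delimited, UTF-8, no quoting or row names.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_tsv` returns a data.frame; `write_tsv` the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write / read a numeric matrix as TSV
#'
#' Row names go into a leading `id` column; used for TPM tables, bulk
#' cohorts and score matrices.
#'
#' @param m Numeric matrix with row and column names.
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
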