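#' Merge exhausted CD8+ subtypes into a binary group assignment
#'
#' Cells whose subtype is one of the exhausted labels become group
#' `"exhausted"`; all other CD8+ cells become `"other"`. Non-CD8 cells are
#' excluded entirely. Labels absent from the metadata vocabulary trigger a
#' warning.
#'
#' @param cell_meta Per-cell metadata data.frame with at least `cell_id`,
#'   `lineage` and `subtype` columns.
#' @param exhausted_labels Subtype labels counting as exhausted; defaults
#'   to the four annotated exhausted CD8+ subtypes
#'   ([EXHAUSTED_SUBTYPES]).
#' @return Data.frame with columns `cell_id` and `group`
#'   ("exhausted"/"other"), one row per CD8+ cell.
#' @export
merge_exhausted <- function(cell_meta, exhausted_labels = EXHAUSTED_SUBTYPES) {
  assert_that(is.data.frame(cell_meta) &&
                all(c("cell_id", "lineage", "subtype") %in% names(cell_meta)),
              "cell_meta must contain cell_id, lineage and subtype")
  vocab <- unique(cell_meta$subtype)
  missing <- setdiff(exhausted_labels, vocab)
  if (length(missing) > 0) {
    warning("exhausted labels absent from metadata: ",
            paste(missing, collapse = ", "))
  }
  cd8 <- cell_meta[cell_meta$lineage == "CD8", , drop = FALSE]
  if (nrow(cd8) == 0) {
    warning("no CD8+ cells in metadata; returning empty assignment")
    return(data.frame(cell_id = character(0), group = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    cell_id = cd8$cell_id,
    group = ifelse(cd8$subtype %in% exhausted_labels, "exhausted", "other"),
    stringsAsFactors = FALSE
  )
}

#' Filter cancer types by exhausted-cell count
#'
#' Cancer types with fewer than `min_exhausted` exhausted CD8+ T cells are
#' removed from the analysis; a type with exactly `min_exhausted` is
#' retained.
#'
#' @param atlas An [expression_atlas()].
#' @param assignment Output of [merge_exhausted()].
#' @param min_exhausted Minimum exhausted-cell count, default 100.
#' @return Character vector of retained cancer-type labels.
#' @export
filter_cancer_types <- function(atlas, assignment, min_exhausted = 100L) {
  assert_that(inherits(atlas, "ExpressionAtlas"), "atlas must be an ExpressionAtlas")
  assert_that(is_count(min_exhausted), "min_exhausted must be a non-negative integer")
  meta <- atlas$cell_meta
  exh_ids <- assignment$cell_id[assignment$group == "exhausted"]
  counts <- table(factor(meta$cancer_type[meta$cell_id %in% exh_ids],
                         levels = unique(meta$cancer_type)))
  retained <- names(counts)[counts >= min_exhausted]
  if (length(retained) == 0) {
    warning("no cancer type passes the exhausted-cell filter")
  }
  retained
}

#' Library-size log-normalization
#'
#' Per cell: `ln(1 + scale * count / library_size)` with the library size
#' taken as the cell's total counts, mirroring the default normalized slot
#' that rank-based single-cell DE is run on. Cells with zero library size
#' yield an all-zero row with a warning. Sparsity is preserved.
#'
#' @param counts Cells-x-genes count matrix (dense or sparse),
#'   non-negative.
#' @param scale Scale factor, default 1e4.
#' @return Sparse normalized matrix of the same dimensions.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  assert_that(is_scalar_number(scale) && scale > 0, "scale must be positive")
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  assert_that(all(m@x >= 0), "counts must be non-negative")
  lib <- Matrix::rowSums(m)
  if (any(lib == 0)) {
    warning(sprintf("%d cell(s) with zero library size normalized to zero",
                    sum(lib == 0)))
  }
  inv <- ifelse(lib > 0, scale / lib, 0)
  out <- Matrix::Diagonal(x = inv) %*% m
  out <- methods::as(out, "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  out
}

#' Per-cancer-type differential expression, exhausted vs. other CD8+
#'
#' For one cancer type: tie-corrected two-sided Wilcoxon rank-sum test per
#' gene on log-normalized expression between exhausted and non-exhausted
#' CD8+ T cells, Benjamini-Hochberg adjustment within the tested gene set,
#' and log2 fold change computed as the difference of log2-transformed
#' group means. A gene is flagged `significant` at `p_adj < alpha` and
#' `upregulated` when additionally `log2fc > 0`.
#'
#' @param atlas An [expression_atlas()].
#' @param cancer_type Cancer-type label to test.
#' @param gene_subset Genes to test (e.g. the mitochondrial universe);
#'   BH adjustment is over exactly this set. Default: all atlas genes.
#' @param assignment Output of [merge_exhausted()].
#' @param alpha Significance threshold on adjusted p, default 0.05.
#' @param eps Pseudocount for the fold change, default 1e-9.
#' @param on Compute group means for the fold change on `"normalized"`
#'   (default) or raw `"counts"`.
#' @param normalized Optional precomputed [normalize_log()] matrix for the
#'   whole atlas (saves recomputation across cancer types).
#' @return A `DifferentialResult`: list with `cancer_type` and `table`
#'   (gene_id, log2fc, p, p_adj, n_exhausted, n_other, significant,
#'   upregulated).
#' @export
differential_expression <- function(atlas, cancer_type,
                                    gene_subset = atlas$gene_ids,
                                    assignment,
                                    alpha = 0.05, eps = 1e-9,
                                    on = c("normalized", "counts"),
                                    normalized = NULL) {
  assert_that(inherits(atlas, "ExpressionAtlas"), "atlas must be an ExpressionAtlas")
  on <- match.arg(on)
  missing_genes <- setdiff(gene_subset, atlas$gene_ids)
  assert_that(length(missing_genes) == 0,
              paste("gene_subset not in atlas:",
                    paste(utils::head(missing_genes, 5), collapse = ", ")))
  meta <- atlas$cell_meta
  grp <- stats::setNames(assignment$group, assignment$cell_id)
  sel <- meta$cancer_type == cancer_type & meta$cell_id %in% assignment$cell_id
  ids <- meta$cell_id[sel]
  groups <- grp[ids]
  n_exh <- sum(groups == "exhausted")
  n_oth <- sum(groups == "other")
  assert_that(n_exh > 0 && n_oth > 0,
              sprintf("cancer type %s: both groups must be non-empty (exhausted=%d, other=%d)",
                      cancer_type, n_exh, n_oth))
  if (is.null(normalized)) normalized <- normalize_log(atlas$counts)
  sub <- as.matrix(normalized[ids, gene_subset, drop = FALSE])
  is_exh <- groups == "exhausted"

  wt <- wilcoxon_matrix(sub, is_exh)
  if (on == "normalized") {
    mean_exh <- colMeans(sub[is_exh, , drop = FALSE])
    mean_oth <- colMeans(sub[!is_exh, , drop = FALSE])
  } else {
    raw <- as.matrix(atlas$counts[ids, gene_subset, drop = FALSE])
    mean_exh <- colMeans(raw[is_exh, , drop = FALSE])
    mean_oth <- colMeans(raw[!is_exh, , drop = FALSE])
  }
  lfc <- log2_fold_change(mean_exh, mean_oth, eps)
  lfc[mean_exh == mean_oth] <- 0
  p_adj <- bh_adjust(wt$p)
  tab <- data.frame(
    gene_id = gene_subset,
    log2fc = unname(lfc),
    p = wt$p,
    p_adj = p_adj,
    n_exhausted = n_exh,
    n_other = n_oth,
    significant = p_adj < alpha,
    upregulated = p_adj < alpha & unname(lfc) > 0,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(cancer_type = cancer_type, table = tab,
                 alpha = alpha, eps = eps, on = on),
            class = "DifferentialResult")
}

#' @export
print.DifferentialResult <- function(x, ...) {
  cat(sprintf("DifferentialResult for %s: %d genes tested (%d exhausted vs %d other cells), %d significant\n",
              x$cancer_type, nrow(x$table), x$table$n_exhausted[1],
              x$table$n_other[1], sum(x$table$significant)))
  invisible(x)
}
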