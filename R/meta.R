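#' Combine per-cancer differential results across cancer types
#'
#' For each gene tested in at least one cancer type: combine the raw
#' Wilcoxon p-values across the cancer types where the gene was tested by
#' Fisher's method ("sumlog"), take the median log2 fold change across
#' those types, and BH-adjust the combined p-values over all emitted
#' genes.
#'
#' @param results List of `DifferentialResult` objects (one per cancer
#'   type).
#' @return A `MetaGeneTable` data.frame: gene_id, k_tested, combined_p,
#'   combined_p_adj, median_log2fc.
#' @export
combine_across_cancers <- function(results) {
  assert_that(is.list(results) && length(results) >= 1,
              "at least one DifferentialResult is required")
  assert_that(all(vapply(results, inherits, logical(1), "DifferentialResult")),
              "results must be DifferentialResult objects")
  genes <- sort(unique(unlist(lapply(results, function(r) r$table$gene_id))))
  pmat <- matrix(NA_real_, nrow = length(genes), ncol = length(results),
                 dimnames = list(genes, NULL))
  lmat <- pmat
  for (j in seq_along(results)) {
    tab <- results[[j]]$table
    pmat[tab$gene_id, j] <- tab$p
    lmat[tab$gene_id, j] <- tab$log2fc
  }
  k_tested <- rowSums(!is.na(pmat))
  combined_p <- vapply(seq_along(genes), function(i) {
    fisher_combine(pmat[i, !is.na(pmat[i, ])])
  }, numeric(1))
  median_lfc <- apply(lmat, 1, stats::median, na.rm = TRUE)
  out <- data.frame(
    gene_id = genes,
    k_tested = as.integer(k_tested),
    combined_p = combined_p,
    combined_p_adj = bh_adjust(combined_p),
    median_log2fc = unname(median_lfc),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("MetaGeneTable", "data.frame")
  out
}

# Normalized descending-rank score shared by the enrichment and exhaustion
# scores: rank 1 = largest value; ties broken by smaller tiebreak value,
# then lexicographic gene id; score = (n - rank + 1)/n in (0, 1].
descending_rank_score <- function(values, tiebreak, gene_ids) {
  ord <- order(-values, tiebreak, gene_ids)
  rank <- integer(length(values))
  rank[ord] <- seq_along(values)
  list(rank = rank, score = (length(values) - rank + 1) / length(values))
}

#' Enrichment rank and score from median fold changes
#'
#' Ranks genes by descending median log2 fold change (rank 1 = largest;
#' ties broken by smaller combined p, then gene id) and converts the rank
#' to a normalized score `(n - rank + 1)/n` in (0, 1], so larger = more
#' enriched in exhausted cells.
#'
#' @param meta A `MetaGeneTable` from [combine_across_cancers()].
#' @return The table with `enrichment_rank` and `enrichment_score` columns
#'   added.
#' @export
enrichment_scores <- function(meta) {
  assert_that(is.data.frame(meta) &&
                all(c("gene_id", "median_log2fc") %in% names(meta)),
              "meta must contain gene_id and median_log2fc")
  tiebreak <- if ("combined_p" %in% names(meta)) meta$combined_p else
    rep(0, nrow(meta))
  rs <- descending_rank_score(meta$median_log2fc, tiebreak, meta$gene_id)
  meta$enrichment_rank <- rs$rank
  meta$enrichment_score <- rs$score
  meta
}

#' Per-cell exhaustion-signature score
#'
#' The mean normalized expression of the five exhaustion markers PDCD1,
#' CTLA4, HAVCR2, LAG3 and TOX, per cell.
#'
#' @param normalized Cells-x-genes normalized expression matrix with gene
#'   column names (see [normalize_log()]).
#' @param marker_genes Marker set; default [EXHAUSTION_MARKERS].
#' @return Named numeric vector of per-cell scores.
#' @export
exhaustion_signature <- function(normalized, marker_genes = EXHAUSTION_MARKERS) {
  missing <- setdiff(marker_genes, colnames(normalized))
  if (length(missing) > 0) {
    stop("missing exhaustion marker gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- normalized[, marker_genes, drop = FALSE]
  score <- if (methods::is(sub, "sparseMatrix")) Matrix::rowMeans(sub) else
    rowMeans(as.matrix(sub))
  stats::setNames(as.numeric(score), rownames(normalized))
}

#' Correlation of gene expression with the exhaustion signature
#'
#' Pearson correlation between each gene's normalized expression and the
#' per-cell exhaustion-signature score across CD8+ T cells, with a
#' t-transform p-value and BH adjustment over the tested genes, and a
#' normalized descending-rank exhaustion score (rank 1 = strongest
#' correlation). Intended for genes already gated as significantly
#' upregulated in exhausted cells at the meta level.
#'
#' In `"pooled"` scope (default) cells of all retained cancer types are
#' pooled; in `"per_cancer_median"` scope r is the median of per-cancer
#' correlations and the p-value uses the median per-cancer cell count.
#'
#' @param normalized Cells-x-genes normalized matrix restricted to the
#'   CD8+ cells of retained cancer types.
#' @param genes Genes to test.
#' @param signature Per-cell signature from [exhaustion_signature()]
#'   (computed on the same cells); if `NULL` it is computed from
#'   `normalized`.
#' @param scope `"pooled"` or `"per_cancer_median"`.
#' @param cancer_type Per-cell cancer-type labels (required for
#'   `per_cancer_median`).
#' @return An `ExhaustionCorrelationTable` data.frame: gene_id, r, p,
#'   p_adj, exhaustion_rank, exhaustion_score. Zero-variance genes get
#'   `NA` r and are excluded from the ranking.
#' @export
exhaustion_correlation <- function(normalized, genes, signature = NULL,
                                   scope = c("pooled", "per_cancer_median"),
                                   cancer_type = NULL) {
  scope <- match.arg(scope)
  missing <- setdiff(genes, colnames(normalized))
  assert_that(length(missing) == 0,
              paste("genes not in matrix:", paste(utils::head(missing, 5), collapse = ", ")))
  if (is.null(signature)) signature <- exhaustion_signature(normalized)
  assert_that(length(signature) == nrow(normalized),
              "signature must have one value per cell")
  mat <- as.matrix(normalized[, genes, drop = FALSE])

  cor_one <- function(m, s) {
    suppressWarnings(as.numeric(stats::cor(m, s, method = "pearson")))
  }
  if (scope == "pooled") {
    r <- cor_one(mat, signature)
    n_eff <- nrow(mat)
  } else {
    assert_that(!is.null(cancer_type) && length(cancer_type) == nrow(mat),
                "per_cancer_median scope needs per-cell cancer_type labels")
    types <- unique(cancer_type)
    rmat <- vapply(types, function(ct) {
      idx <- cancer_type == ct
      cor_one(mat[idx, , drop = FALSE], signature[idx])
    }, numeric(length(genes)))
    rmat <- matrix(rmat, nrow = length(genes))
    r <- apply(rmat, 1, stats::median, na.rm = TRUE)
    r[!is.finite(r)] <- NA_real_
    n_eff <- stats::median(table(cancer_type))
  }
  # p from the t-transform of r
  tstat <- r * sqrt((n_eff - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n_eff - 2)
  p[!is.na(r) & abs(r) >= 1] <- .Machine$double.xmin
  ok <- !is.na(r)
  p_adj <- rep(NA_real_, length(genes))
  p_adj[ok] <- bh_adjust(p[ok])
  rank_full <- rep(NA_integer_, length(genes))
  score_full <- rep(NA_real_, length(genes))
  if (any(ok)) {
    rs <- descending_rank_score(r[ok], p[ok], genes[ok])
    rank_full[ok] <- rs$rank
    score_full[ok] <- rs$score
  }
  out <- data.frame(
    gene_id = genes, r = r, p = p, p_adj = p_adj,
    exhaustion_rank = rank_full, exhaustion_score = score_full,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("ExhaustionCorrelationTable", "data.frame")
  out
}

#' Universality: number of cancer types with significant upregulation
#'
#' Counts, per gene, the cancer types in which the gene is significantly
#' upregulated in exhausted cells (BH-adjusted p < `alpha` and
#' log2FC > 0).
#'
#' @param results List of `DifferentialResult` objects.
#' @param alpha Significance threshold, default 0.05.
#' @return Named integer vector over all genes tested in any type.
#' @export
universality <- function(results, alpha = 0.05) {
  assert_that(is.list(results) && length(results) >= 1,
              "at least one DifferentialResult is required")
  genes <- sort(unique(unlist(lapply(results, function(r) r$table$gene_id))))
  counts <- stats::setNames(integer(length(genes)), genes)
  for (r in results) {
    tab <- r$table
    hit <- tab$gene_id[tab$p_adj < alpha & tab$log2fc > 0]
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

#' Rank final candidate genes
#'
#' Joins the meta table with the exhaustion-correlation table, optionally
#' filters to genes with the highest possible universality (significantly
#' upregulated in every tested cancer type), and orders candidates by
#' descending `enrichment_score + exhaustion_score`, breaking ties by
#' smaller combined p. Genes without an exhaustion score (not gated into
#' the correlation step, or zero variance) contribute 0 for that term and
#' are only retained when the universality filter is off.
#'
#' @param meta `MetaGeneTable` with enrichment scores
#'   ([enrichment_scores()]).
#' @param corr `ExhaustionCorrelationTable`.
#' @param universality_counts Named vector from [universality()].
#' @param require_max_universality If `TRUE` (default), keep only genes
#'   with universality equal to their `k_tested`.
#' @return Data.frame ordered by final rank, with a `final_rank` column.
#' @export
prioritize <- function(meta, corr, universality_counts,
                       require_max_universality = TRUE) {
  assert_that(all(c("enrichment_score", "combined_p") %in% names(meta)),
              "meta must carry enrichment scores; run enrichment_scores() first")
  out <- meta
  out$universality <- as.integer(universality_counts[out$gene_id])
  out$universality[is.na(out$universality)] <- 0L
  idx <- match(out$gene_id, corr$gene_id)
  out$r <- corr$r[idx]
  out$exhaustion_rank <- corr$exhaustion_rank[idx]
  out$exhaustion_score <- corr$exhaustion_score[idx]
  if (require_max_universality) {
    out <- out[out$universality == out$k_tested & out$k_tested > 0, ,
               drop = FALSE]
    if (nrow(out) == 0) {
      warning("no gene is significantly upregulated in every tested cancer type")
      out$final_rank <- integer(0)
      return(out)
    }
  }
  combined <- out$enrichment_score +
    ifelse(is.na(out$exhaustion_score), 0, out$exhaustion_score)
  ord <- order(-combined, out$combined_p, out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
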