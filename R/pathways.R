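#' Quantile normalization across samples
#'
#' Classic rank-mean quantile normalization: within each sample, the k-th
#' smallest value is replaced by the mean of all samples' k-th smallest
#' values; ties within a sample receive the mean of their reference
#' values. Delegates to `limma::normalizeQuantiles`, the standard
#' implementation of this algorithm.
#'
#' @param mat Samples-x-genes numeric matrix (>= 2 samples), no missing
#'   values.
#' @return Matrix of the same shape with a common empirical distribution
#'   across samples.
#' @export
quantile_normalize <- function(mat) {
  assert_that(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  assert_that(nrow(mat) >= 2, "at least two samples are required")
  assert_that(!anyNA(mat), "missing values are not supported")
  out <- t(limma::normalizeQuantiles(t(mat), ties = TRUE))
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-gene tumor vs. normal test on merged, quantile-normalized cohorts
#'
#' Merges the two cohorts, quantile-normalizes the combined matrix to
#' remove cohort-level technical differences (mirroring merged TCGA/GTEx
#' handling), then per gene runs a two-sided tie-corrected Wilcoxon
#' rank-sum test across samples with BH adjustment and a log2 fold change
#' of group means.
#'
#' @param tumor,normal Samples-x-genes matrices with identical gene
#'   columns; each must have >= 2 samples.
#' @param quantile_normalize If `TRUE` (default) merge-and-normalize
#'   before testing; set `FALSE` if the inputs were already normalized
#'   together.
#' @param eps Pseudocount for the fold change, default 1e-9.
#' @return Data.frame: gene_id, log2fc (tumor minus normal), p, p_adj.
#' @export
tumor_normal_gene_test <- function(tumor, normal, quantile_normalize = TRUE,
                                   eps = 1e-9) {
  assert_that(is.matrix(tumor) && is.matrix(normal),
              "tumor and normal must be matrices")
  assert_that(identical(colnames(tumor), colnames(normal)),
              "tumor and normal must share identical gene columns")
  assert_that(nrow(tumor) >= 2 && nrow(normal) >= 2,
              "each group needs at least two samples")
  merged <- rbind(tumor, normal)
  if (quantile_normalize) merged <- quantile_normalize(merged)
  is_tumor <- c(rep(TRUE, nrow(tumor)), rep(FALSE, nrow(normal)))
  wt <- wilcoxon_matrix(merged, is_tumor)
  mean_t <- colMeans(merged[is_tumor, , drop = FALSE])
  mean_n <- colMeans(merged[!is_tumor, , drop = FALSE])
  lfc <- log2_fold_change(mean_t, mean_n, eps)
  lfc[mean_t == mean_n] <- 0
  data.frame(
    gene_id = colnames(tumor),
    log2fc = unname(lfc),
    p = wt$p,
    p_adj = bh_adjust(wt$p),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Pathway dysregulation score with a permutation null
#'
#' Scores one pathway against a differential-expression table. The default
#' variant (`"mean_sig_log2fc"`) is the mean log2 fold change over pathway
#' members that are significant DEGs (`p_adj < alpha`); alternatives are
#' the mean over all tested members (`"mean_all_log2fc"`) and the signed
#' fraction of significant members, up minus down, over the member count
#' (`"sig_fraction_signed"`). Significance comes from a two-sided
#' permutation null: `B` random gene sets of the same size are drawn
#' without replacement from the tested universe and scored identically,
#' giving `perm_p = (1 + #(|score*| >= |score|)) / (B' + 1)` where `B'` is
#' the number of comparable draws. Under the default variant the observed
#' score exists only when the set contains a significant member, so draws
#' without one are excluded from the null rather than scored 0 — the
#' conditioning keeps the p-value valid when significance is sparse.
#'
#' @param deg_table Data.frame with gene_id, log2fc, p_adj (e.g. from
#'   [tumor_normal_gene_test()] or a `DifferentialResult$table`).
#' @param pathway_members Character vector of member genes.
#' @param variant Score variant, see above.
#' @param B Number of permutation draws, default 1000.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param alpha DEG significance threshold, default 0.05.
#' @return List: score (NA with `defined = FALSE` when no member is
#'   tested, or no member is significant under the default variant),
#'   perm_p, n_members_tested, defined.
#' @export
pathway_score <- function(deg_table, pathway_members,
                          variant = c("mean_sig_log2fc", "mean_all_log2fc",
                                      "sig_fraction_signed"),
                          B = 1000L, seed, alpha = 0.05) {
  variant <- match.arg(variant)
  assert_that(is.data.frame(deg_table) &&
                all(c("gene_id", "log2fc", "p_adj") %in% names(deg_table)),
              "deg_table must contain gene_id, log2fc and p_adj")
  assert_that(!missing(seed) && is_count(abs(seed)), "an integer seed is required")
  assert_that(is_count(B) && B >= 1, "B must be a positive integer")
  universe <- deg_table$gene_id
  members <- intersect(pathway_members, universe)
  m <- length(members)
  if (m == 0) {
    return(list(score = NA_real_, perm_p = NA_real_, n_members_tested = 0L,
                defined = FALSE))
  }
  lfc <- stats::setNames(deg_table$log2fc, universe)
  sig <- stats::setNames(deg_table$p_adj < alpha, universe)
  score_fun <- switch(variant,
    mean_sig_log2fc = function(idx) {
      s <- sig[idx]
      if (!any(s)) return(0) else mean(lfc[idx][s])
    },
    mean_all_log2fc = function(idx) mean(lfc[idx]),
    sig_fraction_signed = function(idx) {
      s <- sig[idx]
      (sum(s & lfc[idx] > 0) - sum(s & lfc[idx] < 0)) / length(idx)
    })
  obs <- score_fun(members)
  if (variant == "mean_sig_log2fc" && !any(sig[members])) {
    return(list(score = NA_real_, perm_p = NA_real_,
                n_members_tested = m, defined = FALSE))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  null_scores <- vapply(seq_len(B), function(b) {
    idx <- sample(universe, m, replace = FALSE)
    if (variant == "mean_sig_log2fc" && !any(sig[idx])) return(NA_real_)
    score_fun(idx)
  }, numeric(1))
  # the observed score exists only when the set has a significant member;
  # the null is conditioned on the same event so the p-value stays valid
  # when significance is sparse in the universe
  null_scores <- null_scores[!is.na(null_scores)]
  perm_p <- (1 + sum(abs(null_scores) >= abs(obs) - 1e-12)) /
    (length(null_scores) + 1)
  list(score = obs, perm_p = perm_p, n_members_tested = m, defined = TRUE)
}

#' Score a pathway collection across conditions
#'
#' Runs [pathway_score()] for every pathway of a collection against one
#' DEG table per condition, BH-adjusts the permutation p-values within
#' each condition, and flags significance.
#'
#' @param deg_tables Named list of per-condition DEG tables.
#' @param pathways A [gene_set_collection()].
#' @param variant,B,alpha See [pathway_score()].
#' @param seed Root seed; one child stream per (condition, pathway).
#' @return A `PathwayScoreTable` data.frame in long format: pathway,
#'   condition, score, perm_p, p_adj, significant, n_members_tested,
#'   defined.
#' @export
pathway_score_table <- function(deg_tables, pathways,
                                variant = "mean_sig_log2fc", B = 1000L,
                                seed = 1L, alpha = 0.05) {
  assert_that(is.list(deg_tables) && length(deg_tables) >= 1 &&
                !is.null(names(deg_tables)),
              "deg_tables must be a named list of DEG tables")
  assert_that(inherits(pathways, "GeneSetCollection"),
              "pathways must be a GeneSetCollection")
  rows <- list()
  for (ci in seq_along(deg_tables)) {
    cond <- names(deg_tables)[ci]
    for (pi in seq_along(pathways$sets)) {
      res <- pathway_score(deg_tables[[ci]], pathways$sets[[pi]],
                           variant = variant, B = B,
                           seed = derive_seed(seed, ci * 100003L + pi),
                           alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = names(pathways$sets)[pi], condition = cond,
        score = res$score, perm_p = res$perm_p,
        n_members_tested = res$n_members_tested, defined = res$defined,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (cond in unique(out$condition)) {
    idx <- out$condition == cond & out$defined
    if (any(idx)) out$p_adj[idx] <- bh_adjust(out$perm_p[idx])
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  class(out) <- c("PathwayScoreTable", "data.frame")
  out
}

#' Count significantly dysregulated pathways per condition
#'
#' @param scores A `PathwayScoreTable` (BH-adjusted within condition).
#' @param alpha Threshold on adjusted permutation p, default 0.05.
#' @return Named integer vector, one count per condition. Pathways with an
#'   undefined score are excluded.
#' @export
count_dysregulated <- function(scores, alpha = 0.05) {
  assert_that(is.data.frame(scores) &&
                all(c("condition", "p_adj", "defined") %in% names(scores)),
              "scores must be a PathwayScoreTable")
  conds <- unique(scores$condition)
  vapply(stats::setNames(conds, conds), function(cond) {
    idx <- scores$condition == cond & scores$defined
    sum(scores$p_adj[idx] < alpha, na.rm = TRUE)
  }, integer(1))
}

#' Z-scale pathway scores across conditions
#'
#' Per pathway row: subtract the mean and divide by the sample standard
#' deviation across conditions. Zero-variance rows become all-zero and are
#' flagged through the `constant_rows` attribute.
#'
#' @param score_matrix Pathways-x-conditions numeric matrix (>= 2
#'   conditions); `NA` entries (undefined scores) are ignored in the
#'   moments and propagated.
#' @return Scaled matrix with attribute `constant_rows`.
#' @export
scale_scores <- function(score_matrix) {
  assert_that(is.matrix(score_matrix) && ncol(score_matrix) >= 2,
              "score_matrix needs at least two condition columns")
  mu <- rowMeans(score_matrix, na.rm = TRUE)
  sdv <- apply(score_matrix, 1, stats::sd, na.rm = TRUE)
  constant <- !is.na(sdv) & sdv == 0
  out <- sweep(score_matrix, 1, mu, "-")
  safe_sd <- ifelse(is.na(sdv) | sdv == 0, 1, sdv)
  out <- sweep(out, 1, safe_sd, "/")
  out[constant, ] <- 0
  attr(out, "constant_rows") <- rownames(score_matrix)[constant] %||%
    which(constant)
  out
}

#' Long score table to pathways-x-conditions matrix
#'
#' @param scores A `PathwayScoreTable`.
#' @return Numeric matrix, pathways as rows, conditions as columns, `NA`
#'   for undefined scores.
#' @export
score_matrix <- function(scores) {
  pw <- unique(scores$pathway)
  cond <- unique(scores$condition)
  m <- matrix(NA_real_, length(pw), length(cond), dimnames = list(pw, cond))
  m[cbind(match(scores$pathway, pw), match(scores$condition, cond))] <-
    scores$score
  m
}
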