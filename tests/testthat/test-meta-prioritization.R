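fake_result <- function(ct, genes, p, lfc, n_exh = 200L, n_oth = 200L,
                        alpha = 0.05) {
  p_adj <- bh_adjust(p)
  structure(list(cancer_type = ct, table = data.frame(
    gene_id = genes, log2fc = lfc, p = p, p_adj = p_adj,
    n_exhausted = n_exh, n_other = n_oth,
    significant = p_adj < alpha, upregulated = p_adj < alpha & lfc > 0,
    stringsAsFactors = FALSE)), class = "DifferentialResult")
}

test_that("cross-cancer combination takes Fisher p and median log2FC", {
  genes <- c("g1", "g2")
  res <- list(
    fake_result("A", genes, p = c(0.5, 0.01), lfc = c(-1, 1.5)),
    fake_result("B", genes, p = c(0.5, 0.02), lfc = c(0, 1.5)),
    fake_result("C", genes, p = c(0.9, 0.03), lfc = c(2, 1.5))
  )
  meta <- combine_across_cancers(res)
  g1 <- meta[meta$gene_id == "g1", ]
  g2 <- meta[meta$gene_id == "g2", ]
  expect_equal(g1$median_log2fc, 0)      # median of [-1, 0, 2]
  expect_equal(g2$median_log2fc, 1.5)    # identical across types
  expect_equal(g1$k_tested, 3L)
  expect_equal(fisher_combine(c(0.5, 0.5)),
               combine_across_cancers(res[1:2])[1, "combined_p"])
  expect_true(all(meta$combined_p_adj >= meta$combined_p))
})

test_that("genes tested in a subset of cancers combine over that subset", {
  res <- list(
    fake_result("A", c("g1", "g2"), p = c(0.5, 0.2), lfc = c(1, 2)),
    fake_result("B", "g1", p = 0.5, lfc = 3)
  )
  meta <- combine_across_cancers(res)
  expect_equal(meta$k_tested[meta$gene_id == "g2"], 1L)
  expect_equal(meta$combined_p[meta$gene_id == "g2"], 0.2)  # k=1 identity
  expect_equal(meta$median_log2fc[meta$gene_id == "g1"], 2)
})

test_that("enrichment scores are normalized descending ranks", {
  meta <- data.frame(gene_id = c("a", "b", "c"),
                     median_log2fc = c(2, 1, 0.5),
                     combined_p = c(0.01, 0.02, 0.03))
  sc <- enrichment_scores(meta)
  expect_equal(sc$enrichment_rank, c(1L, 2L, 3L))
  expect_equal(sc$enrichment_score, c(1, 2/3, 1/3))

  # all medians equal: tie rule by combined_p, scores still a permutation
  tied <- data.frame(gene_id = c("a", "b", "c"),
                     median_log2fc = c(1, 1, 1),
                     combined_p = c(0.3, 0.1, 0.2))
  st <- enrichment_scores(tied)
  expect_equal(st$enrichment_rank, c(3L, 1L, 2L))
  expect_setequal(st$enrichment_score, c(1, 2/3, 1/3))

  single <- enrichment_scores(data.frame(gene_id = "only",
                                         median_log2fc = 0,
                                         combined_p = 0.5))
  expect_equal(single$enrichment_rank, 1L)
  expect_equal(single$enrichment_score, 1)
})

test_that("enrichment ranks are scale-free and monotone in log2FC", {
  set.seed(17)
  meta <- data.frame(gene_id = sprintf("g%02d", 1:15),
                     median_log2fc = rnorm(15),
                     combined_p = runif(15))
  base <- enrichment_scores(meta)
  scaled <- meta
  scaled$median_log2fc <- 3.7 * scaled$median_log2fc
  expect_equal(enrichment_scores(scaled)$enrichment_rank,
               base$enrichment_rank)
  # raising one gene's median never worsens its rank
  bumped <- meta
  bumped$median_log2fc[5] <- bumped$median_log2fc[5] + 1
  expect_lte(enrichment_scores(bumped)$enrichment_rank[5],
             base$enrichment_rank[5])
})

test_that("exhaustion signature is the marker mean and errors on absence", {
  m <- matrix(c(1, 2, 3, 4, 5,
                0, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("cellA", "cellB"), EXHAUSTION_MARKERS))
  sig <- exhaustion_signature(m)
  expect_equal(unname(sig), c(3, 0))
  expect_error(exhaustion_signature(m[, 1:4, drop = FALSE]), "TOX")
})

test_that("Tex cells score higher on the signature than other CD8 cells", {
  diffs <- vapply(1:20, function(s) {
    a <- generate_tcell_atlas(small_params(seed = 900 + s, marker_log2fc = 2,
                                           n_cancer_types = 1L))
    asg <- merge_exhausted(a$cell_meta)
    sig <- exhaustion_signature(normalize_log(a$counts)[asg$cell_id, ])
    mean(sig[asg$group == "exhausted"]) - mean(sig[asg$group == "other"])
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("exhaustion correlation behaves on anchor cases", {
  set.seed(23)
  n <- 80
  sig <- rnorm(n, mean = 2)
  m <- cbind(self = sig,                      # identical to the signature
             noisy = sig + rnorm(n, sd = 2),
             flat = rep(1, n))                # zero variance
  rownames(m) <- sprintf("c%02d", 1:n)
  tab <- exhaustion_correlation(m, colnames(m), signature = sig)
  expect_equal(tab$r[tab$gene_id == "self"], 1)
  expect_gt(tab$r[tab$gene_id == "noisy"], 0)
  expect_true(is.na(tab$r[tab$gene_id == "flat"]))       # excluded
  expect_true(is.na(tab$exhaustion_rank[tab$gene_id == "flat"]))
  ranked <- tab[!is.na(tab$exhaustion_rank), ]
  expect_setequal(ranked$exhaustion_rank, seq_len(nrow(ranked)))
  expect_equal(ranked$exhaustion_score,
               (nrow(ranked) - ranked$exhaustion_rank + 1) / nrow(ranked))
})

test_that("a planted gene outcorrelates a matched null gene", {
  wins <- vapply(1:20, function(s) {
    a <- generate_tcell_atlas(small_params(seed = 1500 + s))
    asg <- merge_exhausted(a$cell_meta)
    norm <- normalize_log(a$counts)[asg$cell_id, ]
    tab <- exhaustion_correlation(norm, c("PLANT0001", "GENE00001"))
    tab$r[tab$gene_id == "PLANT0001"] > tab$r[tab$gene_id == "GENE00001"]
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("universality counts significant upregulation only", {
  genes <- c("up_all", "down_one", "never")
  res <- lapply(c("A", "B", "C"), function(ct) {
    lfc <- c(1, if (ct == "B") -1 else 1, 0.1)
    p <- c(1e-6, 1e-6, 0.9)
    fake_result(ct, genes, p = p, lfc = lfc)
  })
  uni <- universality(res)
  expect_equal(uni[["up_all"]], 3L)
  expect_equal(uni[["down_one"]], 2L)  # significant-but-down not counted
  expect_equal(uni[["never"]], 0L)
})

test_that("prioritization filters on universality and orders by score sum", {
  meta <- enrichment_scores(data.frame(
    gene_id = c("a", "b", "c"), k_tested = 3L,
    combined_p = c(1e-5, 1e-6, 0.5),
    combined_p_adj = c(3e-5, 3e-6, 0.5),
    median_log2fc = c(1.2, 2.0, 0.1)))
  corr <- data.frame(gene_id = c("a", "b"), r = c(0.9, 0.4),
                     p = c(1e-4, 0.01), p_adj = c(2e-4, 0.01),
                     exhaustion_rank = c(1L, 2L),
                     exhaustion_score = c(1, 0.5))
  uni <- c(a = 3L, b = 3L, c = 1L)
  top <- prioritize(meta, corr, uni)
  # a: enrichment 2/3 + exhaustion 1 = 5/3 beats b: 1 + 1/2 = 3/2
  expect_equal(top$gene_id, c("a", "b"))
  expect_equal(top$final_rank, 1:2)
  expect_false("c" %in% top$gene_id)

  all_rows <- prioritize(meta, corr, uni, require_max_universality = FALSE)
  expect_equal(nrow(all_rows), nrow(meta))  # flag off keeps every gene
  expect_identical(all_rows, prioritize(meta, corr, uni,
                                        require_max_universality = FALSE))

  empty <- suppressWarnings(prioritize(meta, corr, c(a = 0L, b = 0L, c = 0L)))
  expect_equal(nrow(empty), 0L)
})
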