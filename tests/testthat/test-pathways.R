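test_that("quantile normalization equalizes sample distributions", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn["s1", ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn["s2", ]), c(2.5, 3.5, 4.5))

  ident <- rbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(ident), ident)  # identical samples unchanged

  expect_error(quantile_normalize(matrix(1:3, nrow = 1)), "two samples")
  bad <- matrix(c(1, NA, 2, 3), 2)
  expect_error(quantile_normalize(bad), "missing")
})

test_that("quantile normalization post-conditions hold on random matrices", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rlnorm(8 * 40), nrow = 8)
    qn <- quantile_normalize(m)
    sorted <- apply(qn, 1, sort)
    expect_lt(max(abs(sweep(sorted, 1, sorted[, 1]))), 1e-12)
    expect_lt(max(abs(quantile_normalize(qn) - qn)), 1e-12)  # idempotent
  }
})

test_that("tumor/normal gene test recovers a planted shift", {
  # +1 log2 shift on 10 of 200 genes, with a cohort batch factor that the
  # merged quantile normalization must absorb
  pw <- gene_set_collection(list(hit = sprintf("h%02d", 1:10)))
  hits <- vapply(1:20, function(s) {
    cc <- generate_bulk_cohort(30, 30, pw, shifted_pathways = c(hit = 1),
                               seed = 600 + s, batch_log2 = 0.5,
                               n_background = 190)
    tab <- tumor_normal_gene_test(cc$tumor, cc$normal)
    tab$p_adj[tab$gene_id == "h01"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 19)

  # identical distributions: null p roughly uniform
  cc0 <- generate_bulk_cohort(30, 30, pw, seed = 77, n_background = 40)
  tab0 <- tumor_normal_gene_test(cc0$tumor, cc0$normal)
  expect_gt(suppressWarnings(ks.test(tab0$p, "punif")$p.value), 0.01)
  expect_error(tumor_normal_gene_test(cc0$tumor[1, , drop = FALSE],
                                      cc0$normal),
               "two samples")
})

test_that("the per-gene bulk test reuses the tie-corrected Wilcoxon", {
  set.seed(12)
  tumor <- matrix(rlnorm(10 * 4), 10, dimnames = list(NULL, paste0("g", 1:4)))
  normal <- matrix(rlnorm(12 * 4), 12, dimnames = list(NULL, paste0("g", 1:4)))
  tab <- tumor_normal_gene_test(tumor, normal, quantile_normalize = FALSE)
  for (j in 1:4) {
    ref <- wilcoxon_rank_sum(tumor[, j], normal[, j], mode = "normal")$p
    expect_equal(tab$p[j], ref)
  }
})

test_that("pathway scores follow the stated variant definitions", {
  deg <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(1, 1, -2, 0.1),
                    p_adj = c(0.01, 0.001, 0.2, 0.8))
  res <- pathway_score(deg, c("a", "b"), B = 99, seed = 1)
  expect_equal(res$score, 1)  # all members significant at log2FC +1
  expect_true(res$defined)

  none <- pathway_score(deg, c("c", "d"), B = 99, seed = 1)
  expect_false(none$defined)  # no significant member
  expect_true(is.na(none$score))

  outside <- pathway_score(deg, c("zz1", "zz2"), B = 99, seed = 1)
  expect_false(outside$defined)
  expect_equal(outside$n_members_tested, 0L)

  allvar <- pathway_score(deg, c("a", "c"), variant = "mean_all_log2fc",
                          B = 99, seed = 1)
  expect_equal(allvar$score, mean(c(1, -2)))
  sgn <- pathway_score(deg, c("a", "b", "c", "d"),
                       variant = "sig_fraction_signed", B = 99, seed = 1)
  expect_equal(sgn$score, (2 - 0) / 4)

  # deterministic given seed
  r1 <- pathway_score(deg, c("a", "b"), B = 199, seed = 42)
  r2 <- pathway_score(deg, c("a", "b"), B = 199, seed = 42)
  expect_identical(r1, r2)
})

test_that("permutation p-values are never zero and bounded below", {
  # widespread modest significance in the universe so random draws carry
  # informative scores; the pathway's members are the only strong DEGs
  set.seed(88)
  deg <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    log2fc = c(rep(5, 5), rnorm(95, sd = 0.3)),
                    p_adj = c(rep(1e-6, 5), runif(95, 0, 0.04)))
  res <- pathway_score(deg, sprintf("g%03d", 1:5), B = 200, seed = 9)
  expect_gte(res$perm_p, 1 / 201)
  expect_lte(res$perm_p, 0.05)
  # perfectly null scores cannot reach p below the resolution bound
  null_deg <- data.frame(gene_id = sprintf("g%03d", 1:50),
                         log2fc = rep(1, 50), p_adj = rep(1e-6, 50))
  flat <- pathway_score(null_deg, sprintf("g%03d", 1:5), B = 200, seed = 9)
  expect_equal(flat$perm_p, 1)  # every draw ties the observed score
})

test_that("a planted dysregulated pathway is detected against background", {
  # a coherent +1 pathway inside a transcriptome with widespread modest
  # bidirectional dysregulation (the regime where the significant-member
  # mean score has an informative permutation null)
  pw <- gene_set_collection(list(
    planted = sprintf("h%02d", 1:12),
    bg_up = sprintf("u%03d", 1:100),
    bg_down = sprintf("d%03d", 1:100)))
  shifts <- c(planted = 1, bg_up = 0.4, bg_down = -0.4)
  detected <- vapply(1:10, function(s) {
    cc <- generate_bulk_cohort(30, 30, pw, shifted_pathways = shifts,
                               seed = 800 + s)
    tab <- tumor_normal_gene_test(cc$tumor, cc$normal)
    scores <- pathway_score_table(list(cond = tab), pw, B = 500,
                                  seed = 800 + s)
    scores$significant[scores$pathway == "planted"]
  }, logical(1))
  expect_gte(sum(detected), 9)
})

test_that("dysregulated-pathway counts respect alpha monotonicity", {
  scores <- data.frame(
    pathway = rep(c("p1", "p2", "p3"), 2),
    condition = rep(c("c1", "c2"), each = 3),
    score = 1, perm_p = c(0.001, 0.2, 0.9, 0.01, 0.04, 0.5),
    defined = TRUE)
  scores$p_adj <- NA_real_
  for (cond in unique(scores$condition)) {
    idx <- scores$condition == cond
    scores$p_adj[idx] <- bh_adjust(scores$perm_p[idx])
  }
  c05 <- count_dysregulated(scores, 0.05)
  c01 <- count_dysregulated(scores, 0.01)
  expect_true(all(c01 <= c05))
  all_null <- scores
  all_null$p_adj <- 1
  expect_equal(unname(count_dysregulated(all_null)), c(0L, 0L))
})

test_that("score scaling is a per-pathway z-score with sample sd", {
  m <- rbind(p1 = c(1, 2, 3), p2 = c(5, 5, 5))
  sc <- scale_scores(m)
  expect_equal(unname(sc["p1", ]), c(-1, 0, 1))
  expect_equal(unname(sc["p2", ]), c(0, 0, 0))        # constant -> zeros
  expect_true("p2" %in% attr(sc, "constant_rows"))
  set.seed(2)
  r <- matrix(rnorm(5 * 4), 5)
  z <- scale_scores(r)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5))
})

test_that("long score tables reshape into pathway-by-condition matrices", {
  scores <- data.frame(pathway = c("p1", "p2", "p1", "p2"),
                       condition = c("c1", "c1", "c2", "c2"),
                       score = c(1, NA, 3, 4), defined = c(TRUE, FALSE, TRUE, TRUE))
  m <- score_matrix(scores)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["p1", "c2"], 3)
  expect_true(is.na(m["p2", "c1"]))
})
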