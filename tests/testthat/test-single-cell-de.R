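make_meta <- function(subtypes, lineages = NULL) {
  n <- length(subtypes)
  data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    cancer_type = "CT01",
    patient_id = "P01",
    lineage = lineages %||% rep("CD8", n),
    subtype = subtypes,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("exhausted-subtype merging uses the four annotated labels", {
  meta <- make_meta(c("GZMK+ Tex", "TCF7+ Tex", "OXPHOX- Tex",
                      "terminal Tex", "CD8 Tem", "CD8 Tn"))
  asg <- merge_exhausted(meta)
  expect_equal(asg$group, c(rep("exhausted", 4), rep("other", 2)))
})

test_that("non-CD8 cells are excluded and missing labels warn", {
  meta <- make_meta(c("terminal Tex", "CD4 Tconv", "CD8 Tem"),
                    lineages = c("CD8", "CD4", "CD8"))
  asg <- suppressWarnings(merge_exhausted(meta))
  expect_equal(nrow(asg), 2L)
  expect_false("c002" %in% asg$cell_id)
  expect_warning(merge_exhausted(meta), "absent")
  only_cd4 <- make_meta("CD4 Tconv", lineages = "CD4")
  expect_warning(
    expect_warning(asg0 <- merge_exhausted(only_cd4), "no CD8"),
    "absent")
  expect_equal(nrow(asg0), 0L)
})

test_that("the cancer-type filter applies the fewer-than-100 rule", {
  build <- function(n_exh, ct) {
    data.frame(cell_id = sprintf("%s_c%03d", ct, 1:(n_exh + 20)),
               cancer_type = ct, patient_id = "P",
               lineage = "CD8",
               subtype = c(rep("terminal Tex", n_exh), rep("CD8 Tem", 20)),
               stringsAsFactors = FALSE)
  }
  meta <- rbind(build(99, "CT_low"), build(100, "CT_ok"))
  counts <- Matrix::Matrix(1, nrow = nrow(meta), ncol = 3, sparse = TRUE)
  atlas <- expression_atlas(counts, gene_ids = c("g1", "g2", "g3"),
                            cell_meta = meta)
  asg <- merge_exhausted(meta, exhausted_labels = "terminal Tex")
  retained <- filter_cancer_types(atlas, asg, min_exhausted = 100)
  expect_equal(retained, "CT_ok")          # 99 excluded, 100 retained
  expect_setequal(filter_cancer_types(atlas, asg, min_exhausted = 0),
                  c("CT_low", "CT_ok"))
})

test_that("log-normalization follows its closed form", {
  m <- matrix(c(10, 0, 0, 5, 5, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  norm <- normalize_log(m, scale = 1e4)
  expect_equal(norm["a", "g1"], log(1 + 1e4))  # count = library size
  expect_equal(norm["a", "g1"], 9.2104, tolerance = 1e-4)
  expect_equal(norm["a", "g2"], 0)             # zero counts stay zero
  # doubling all counts of a cell leaves normalized values unchanged
  norm2 <- normalize_log(2 * m, scale = 1e4)
  expect_equal(as.matrix(norm2), as.matrix(norm))
  expect_error(normalize_log(matrix(-1)), "non-negative")
  zed <- matrix(c(1, 0, 2, 0), 2, dimnames = list(c("a", "b"), c("g", "h")))
  expect_warning(nz <- normalize_log(zed), "zero library")
  expect_equal(as.numeric(nz["b", ]), c(0, 0))
})

test_that("differential expression recovers a planted gene with power", {
  hits <- vapply(1:20, function(s) {
    a <- generate_tcell_atlas(atlas_sim_params(
      n_cancer_types = 1L, patients_per_type = 2L, cells_per_patient = 625L,
      subtype_proportions = c("terminal Tex" = 0.4, "CD8 Tem" = 0.4,
                              "CD4 Tconv" = 0.2),
      n_genes = 60L, n_planted = 1L, planted_log2fc = 2, seed = 7000 + s))
    asg <- merge_exhausted(a$cell_meta, exhausted_labels = "terminal Tex")
    de <- differential_expression(a, "CT01", assignment = asg,
                                  gene_subset = setdiff(a$gene_ids,
                                                        EXHAUSTION_MARKERS))
    row <- de$table[de$table$gene_id == "PLANT0001", ]
    row$p_adj < 0.05 && row$log2fc > 0
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("constant genes and empty groups are handled", {
  # the all-zero gene is constant in normalized expression for any cell
  meta <- make_meta(c(rep("terminal Tex", 5), rep("CD8 Tem", 5)))
  counts <- cbind(flat = rep(0, 10), varying = c(rep(1, 5), 6:10))
  atlas <- expression_atlas(Matrix::Matrix(counts, sparse = TRUE),
                            cell_meta = meta)
  asg <- merge_exhausted(meta, exhausted_labels = "terminal Tex")
  de <- differential_expression(atlas, "CT01", assignment = asg)
  flat <- de$table[de$table$gene_id == "flat", ]
  expect_equal(flat$p, 1)
  expect_equal(flat$log2fc, 0)

  # atlas with only exhausted cells: DE refuses
  tex_meta <- make_meta(rep("terminal Tex", 6))
  tex_atlas <- expression_atlas(Matrix::Matrix(1, 6, 2, sparse = TRUE),
                                gene_ids = c("g1", "g2"), cell_meta = tex_meta)
  expect_error(differential_expression(tex_atlas, "CT01",
                                       assignment = merge_exhausted(tex_meta, exhausted_labels = "terminal Tex")),
               "non-empty")
})

test_that("BH adjustment is over exactly the tested gene subset", {
  a <- generate_tcell_atlas(small_params(seed = 31, n_cancer_types = 1L))
  asg <- merge_exhausted(a$cell_meta)
  subset <- a$gene_ids[1:20]
  de <- differential_expression(a, "CT01", gene_subset = subset,
                                assignment = asg)
  expect_equal(de$table$gene_id, subset)
  expect_equal(de$table$p_adj, bh_oracle(de$table$p), tolerance = 1e-12)
  expect_true(all(de$table$p_adj >= de$table$p))
})

test_that("DE is invariant to cell and gene ordering", {
  a <- generate_tcell_atlas(small_params(seed = 13, n_cancer_types = 1L,
                                         cells_per_patient = 60L,
                                         n_genes = 20L))
  asg <- merge_exhausted(a$cell_meta)
  de1 <- differential_expression(a, "CT01", assignment = asg)

  set.seed(1)
  cell_perm <- sample(nrow(a$counts))
  gene_perm <- sample(ncol(a$counts))
  a2 <- expression_atlas(a$counts[cell_perm, gene_perm],
                         gene_ids = a$gene_ids[gene_perm],
                         cell_meta = a$cell_meta[cell_perm, ])
  de2 <- differential_expression(a2, "CT01",
                                 assignment = merge_exhausted(a2$cell_meta))
  t1 <- de1$table[order(de1$table$gene_id), ]
  t2 <- de2$table[order(de2$table$gene_id), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})
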