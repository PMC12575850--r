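#' Generate a synthetic cell-type TPM table
#'
#' Emulates a consensus single-cell TPM table over many cell types (81 by
#' default, matching the scale of the Human Protein Atlas consensus data):
#' rows are genes, columns are cell types, one of which is the T-cell
#' column. Genes listed in `planted_tcell_specific` receive positive TPM in
#' the T-cell column only; one designated control gene is ubiquitously and
#' evenly expressed; remaining genes get independent lognormal TPM values.
#'
#' @param n_celltypes Number of cell types (>= 2); default 81.
#' @param n_genes Total number of genes, including planted and control.
#' @param planted_tcell_specific Character vector of gene ids expressed
#'   only in T cells.
#' @param seed Integer seed; the output is a pure function of the inputs.
#' @param tcell_label Column name of the T-cell type.
#' @return A genes-x-cell-types numeric matrix of TPM values, with an
#'   attribute `tcell_column` naming the T-cell column and a row
#'   `UBIQ_CONTROL` as the ubiquitous control gene.
#' @export
generate_celltype_tpm <- function(n_celltypes = 81L, n_genes = 100L,
                                  planted_tcell_specific = character(0),
                                  seed = 1L, tcell_label = "T-cell") {
  assert_that(is_count(n_celltypes) && n_celltypes >= 2,
              "n_celltypes must be an integer >= 2")
  n_planted <- length(planted_tcell_specific)
  assert_that(is_count(n_genes) && n_genes >= n_planted + 1,
              "n_genes must accommodate planted genes plus a control gene")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(derive_seed(seed, 0L))

  celltypes <- c(tcell_label,
                 sprintf("celltype_%02d", seq_len(n_celltypes - 1L)))
  n_background <- n_genes - n_planted - 1L
  gene_ids <- c(planted_tcell_specific, "UBIQ_CONTROL",
                if (n_background > 0) sprintf("BG%05d", seq_len(n_background)))
  tpm <- matrix(stats::rlnorm(n_genes * n_celltypes, meanlog = 2, sdlog = 1.2),
                nrow = n_genes, ncol = n_celltypes,
                dimnames = list(gene_ids, celltypes))
  if (n_planted > 0) {
    tpm[seq_len(n_planted), ] <- 0
    tpm[seq_len(n_planted), tcell_label] <-
      stats::rlnorm(n_planted, meanlog = 4, sdlog = 0.3)
  }
  # ubiquitous control: high, even expression everywhere
  tpm["UBIQ_CONTROL", ] <- stats::rlnorm(n_celltypes, meanlog = 5, sdlog = 0.05)
  attr(tpm, "tcell_column") <- tcell_label
  tpm
}

#' Generate a synthetic paired tumor/normal bulk cohort
#'
#' Emulates two merged bulk expression cohorts (tumor and normal) over the
#' genes of a pathway collection: lognormal expression with per-gene
#' baselines shared between conditions, a log2 shift added to the tumor
#' mean of every member of each pathway listed in `shifted_pathways`
#' (shifts accumulate for genes in several shifted pathways), and an
#' optional multiplicative batch factor applied to all tumor samples to
#' exercise quantile normalization.
#'
#' @param n_tumor,n_normal Positive sample counts per condition.
#' @param pathways A [gene_set_collection()]; the union of its members
#'   defines the gene universe (plus `n_background` unassigned genes).
#' @param shifted_pathways Named numeric vector: pathway name -> log2 shift
#'   applied to tumor means of its members. Names must be pathways in
#'   `pathways`.
#' @param seed Integer seed.
#' @param batch_log2 Sample-level log2 batch offset added to all tumor
#'   samples (default 0 = no batch effect).
#' @param n_background Extra background genes outside every pathway.
#' @param sdlog Biological lognormal spread on the natural-log scale.
#' @return List with `tumor` and `normal` samples-x-genes matrices and
#'   `gene_ids`.
#' @export
generate_bulk_cohort <- function(n_tumor, n_normal, pathways,
                                 shifted_pathways = numeric(0), seed = 1L,
                                 batch_log2 = 0, n_background = 0L,
                                 sdlog = 0.5) {
  assert_that(is_count(n_tumor) && n_tumor >= 1 &&
                is_count(n_normal) && n_normal >= 1,
              "sample counts must be positive integers")
  assert_that(inherits(pathways, "GeneSetCollection"),
              "pathways must be a GeneSetCollection")
  if (length(shifted_pathways) > 0) {
    assert_that(!is.null(names(shifted_pathways)) &&
                  all(names(shifted_pathways) %in% names(pathways)),
                "shifted_pathways names must be pathways in the collection")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(derive_seed(seed, 0L))

  gene_ids <- sort(unique(unlist(pathways$sets, use.names = FALSE)))
  if (n_background > 0) {
    gene_ids <- c(gene_ids, sprintf("BGGENE%05d", seq_len(n_background)))
  }
  n_genes <- length(gene_ids)
  base_log2 <- stats::rnorm(n_genes, mean = 6, sd = 1.5)
  shift <- stats::setNames(rep(0, n_genes), gene_ids)
  for (pw in names(shifted_pathways)) {
    members <- intersect(pathways$sets[[pw]], gene_ids)
    shift[members] <- shift[members] + shifted_pathways[[pw]]
  }
  draw <- function(n, log2_mean) {
    m <- matrix(2^rep(log2_mean, each = n) *
                  stats::rlnorm(n * n_genes, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                nrow = n, ncol = n_genes)
    colnames(m) <- gene_ids
    m
  }
  tumor <- draw(n_tumor, base_log2 + shift + batch_log2)
  normal <- draw(n_normal, base_log2)
  rownames(tumor) <- sprintf("tumor_%03d", seq_len(n_tumor))
  rownames(normal) <- sprintf("normal_%03d", seq_len(n_normal))
  list(tumor = tumor, normal = normal, gene_ids = gene_ids)
}
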