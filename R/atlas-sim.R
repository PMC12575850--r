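#' Exhausted CD8+ subtype labels and exhaustion markers
#'
#' The four annotated exhausted CD8+ T-cell subtypes that the screen merges
#' into a single "exhausted" group, and the five-gene exhaustion signature.
#' @export
EXHAUSTED_SUBTYPES <- c("GZMK+ Tex", "TCF7+ Tex", "OXPHOX- Tex", "terminal Tex")

#' @rdname EXHAUSTED_SUBTYPES
#' @export
EXHAUSTION_MARKERS <- c("PDCD1", "CTLA4", "HAVCR2", "LAG3", "TOX")

default_subtype_proportions <- function() {
  c("terminal Tex" = 0.15, "GZMK+ Tex" = 0.10, "TCF7+ Tex" = 0.10,
    "OXPHOX- Tex" = 0.05, "CD8 Tem" = 0.20, "CD8 Tn" = 0.20,
    "CD4 Tconv" = 0.20)
}

# Subtype label -> lineage. Exhausted subtypes are CD8 by definition;
# otherwise the label string decides, defaulting to CD8 for unrecognized
# T-cell subtype names.
subtype_lineage <- function(labels) {
  lineage <- rep("CD8", length(labels))
  lineage[grepl("CD4", labels, fixed = TRUE)] <- "CD4"
  lineage[grepl("NK|other|Myeloid|B cell", labels)] <- "other"
  lineage[labels %in% EXHAUSTED_SUBTYPES] <- "CD8"
  lineage
}

#' Simulation parameters for the synthetic T-cell atlas
#'
#' Validated parameter bundle for [generate_tcell_atlas()]. Defaults mirror
#' the study conditions the pipeline is exercised under: several cancer
#' types with a few patients each, CD8+ subtype composition containing the
#' four exhausted subtypes plus non-exhausted CD8 and a CD4 fraction, and a
#' negative-binomial count model with lognormal per-cell library-size
#' factors.
#'
#' @param n_cancer_types Number of cancer types.
#' @param patients_per_type Patients simulated per cancer type.
#' @param cells_per_patient Cells per patient.
#' @param subtype_proportions Named numeric vector of subtype fractions,
#'   summing to 1; must contain at least one exhausted label (see
#'   [EXHAUSTED_SUBTYPES]) and one non-exhausted label.
#' @param n_genes Number of genes (>= n_planted + 5 markers).
#' @param n_planted Number of planted candidate genes upregulated in
#'   exhausted cells across all cancer types.
#' @param planted_log2fc Log2 effect applied to planted genes' means in
#'   exhausted cells.
#' @param marker_log2fc Log2 effect applied to the five exhaustion markers
#'   in exhausted cells.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param library_size_mean Expected total counts per cell.
#' @param seed Root seed; child streams are derived per cancer type so
#'   subsetting is reproducible.
#' @return A validated list of class `AtlasSimParams`.
#' @export
atlas_sim_params <- function(n_cancer_types = 12L,
                             patients_per_type = 4L,
                             cells_per_patient = 250L,
                             subtype_proportions = default_subtype_proportions(),
                             n_genes = 500L,
                             n_planted = 1L,
                             planted_log2fc = 2,
                             marker_log2fc = 2,
                             nb_dispersion = 0.5,
                             library_size_mean = 2000,
                             seed = 1L) {
  assert_that(is_count(n_cancer_types) && n_cancer_types >= 1,
              "n_cancer_types must be a positive integer")
  assert_that(is_count(patients_per_type) && patients_per_type >= 1,
              "patients_per_type must be a positive integer")
  assert_that(is_count(cells_per_patient) && cells_per_patient >= 1,
              "cells_per_patient must be a positive integer")
  assert_that(is.numeric(subtype_proportions) &&
                !is.null(names(subtype_proportions)) &&
                all(nzchar(names(subtype_proportions))),
              "subtype_proportions must be a named numeric vector")
  assert_that(all(subtype_proportions >= 0),
              "subtype proportions must be non-negative")
  assert_that(abs(sum(subtype_proportions) - 1) <= 1e-9,
              "subtype_proportions must sum to 1")
  assert_that(is_count(n_genes) && n_genes >= 1,
              "n_genes must be a positive integer")
  assert_that(is_count(n_planted), "n_planted must be a non-negative integer")
  assert_that(n_planted + length(EXHAUSTION_MARKERS) <= n_genes,
              "n_planted + 5 marker genes must not exceed n_genes")
  assert_that(is_scalar_number(planted_log2fc) && planted_log2fc >= 0,
              "planted_log2fc must be a non-negative number")
  assert_that(is_scalar_number(marker_log2fc) && marker_log2fc >= 0,
              "marker_log2fc must be a non-negative number")
  assert_that(is_scalar_number(nb_dispersion) && nb_dispersion > 0,
              "nb_dispersion must be positive")
  assert_that(is_scalar_number(library_size_mean) && library_size_mean > 0,
              "library_size_mean must be positive")
  assert_that(is_count(abs(seed)), "seed must be an integer")
  has_exhausted <- any(names(subtype_proportions) %in% EXHAUSTED_SUBTYPES)
  non_exh <- setdiff(names(subtype_proportions), EXHAUSTED_SUBTYPES)
  assert_that(length(non_exh) >= 1,
              "subtype_proportions must include a non-exhausted label")
  if (n_planted > 0 && !has_exhausted) {
    stop("planted genes require at least one exhausted subtype label",
         call. = FALSE)
  }
  structure(list(
    n_cancer_types = as.integer(n_cancer_types),
    patients_per_type = as.integer(patients_per_type),
    cells_per_patient = as.integer(cells_per_patient),
    subtype_proportions = subtype_proportions,
    n_genes = as.integer(n_genes),
    n_planted = as.integer(n_planted),
    planted_log2fc = planted_log2fc,
    marker_log2fc = marker_log2fc,
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean,
    seed = as.integer(seed)
  ), class = "AtlasSimParams")
}

#' Generate a synthetic pan-cancer T-cell atlas
#'
#' Draws a cells-x-genes count matrix from a negative-binomial model with
#' lognormal per-cell library-size factors and lognormal per-patient
#' offsets. The five exhaustion markers (PDCD1, CTLA4, HAVCR2, LAG3, TOX)
#' and `n_planted` candidate genes have their mean expression multiplied by
#' `2^marker_log2fc` (resp. `2^planted_log2fc`) in cells whose subtype is
#' one of the exhausted labels, in every cancer type; all other genes have
#' identical means in both groups. Marker and planted genes are assigned
#' moderate baseline abundance (at or above the median gene), reflecting
#' that the real markers are robustly detected in CD8+ T cells.
#'
#' The generator is a pure function of `params`: one child random stream is
#' derived per cancer type from the root seed.
#'
#' @param params An [atlas_sim_params()] object.
#' @return An object of class `ExpressionAtlas`: a list with `counts`
#'   (sparse cells-x-genes dgCMatrix), `gene_ids`, `cell_meta` (data.frame
#'   with cell_id, cancer_type, patient_id, lineage, subtype) and
#'   `planted_genes`.
#' @export
generate_tcell_atlas <- function(params) {
  assert_that(inherits(params, "AtlasSimParams"),
              "params must come from atlas_sim_params()")
  p <- params
  markers <- EXHAUSTION_MARKERS
  n_other <- p$n_genes - length(markers) - p$n_planted
  planted <- if (p$n_planted > 0) sprintf("PLANT%04d", seq_len(p$n_planted)) else character(0)
  background <- if (n_other > 0) sprintf("GENE%05d", seq_len(n_other)) else character(0)
  gene_ids <- c(markers, planted, background)

  # baseline relative abundance, shared across cancer types
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(derive_seed(p$seed, 0L))
  rel <- stats::rgamma(p$n_genes, shape = 0.7, rate = 1)
  rel <- pmax(rel, 1e-6)
  floor_level <- stats::median(rel)
  special <- seq_len(length(markers) + p$n_planted)
  rel[special] <- pmax(rel[special], floor_level)
  rel <- rel / sum(rel)

  fc <- rep(1, p$n_genes)
  fc[seq_along(markers)] <- 2^p$marker_log2fc
  if (p$n_planted > 0) {
    fc[length(markers) + seq_len(p$n_planted)] <- 2^p$planted_log2fc
  }

  labels <- names(p$subtype_proportions)
  lineages <- subtype_lineage(labels)
  size_nb <- 1 / p$nb_dispersion
  cells_per_type <- p$patients_per_type * p$cells_per_patient

  blocks <- vector("list", p$n_cancer_types)
  meta <- vector("list", p$n_cancer_types)
  for (ct in seq_len(p$n_cancer_types)) {
    set.seed(derive_seed(p$seed, ct))
    ct_label <- sprintf("CT%02d", ct)
    patient <- rep(seq_len(p$patients_per_type), each = p$cells_per_patient)
    pat_fac <- stats::rlnorm(p$patients_per_type, meanlog = -0.02, sdlog = 0.2)
    subtype <- sample(labels, cells_per_type, replace = TRUE,
                      prob = p$subtype_proportions)
    lib_fac <- stats::rlnorm(cells_per_type, meanlog = -0.045, sdlog = 0.3)
    cell_scale <- p$library_size_mean * lib_fac * pat_fac[patient]
    exh <- subtype %in% EXHAUSTED_SUBTYPES

    mu <- tcrossprod(cell_scale, rel)         # cells x genes baseline
    if (any(exh) && any(fc != 1)) {
      mu[exh, ] <- mu[exh, ] * rep(fc, each = sum(exh))
    }
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = size_nb),
      nrow = cells_per_type, ncol = p$n_genes)
    blocks[[ct]] <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    meta[[ct]] <- data.frame(
      cell_id = sprintf("%s_P%02d_C%04d", ct_label, patient,
                        seq_len(cells_per_type)),
      cancer_type = ct_label,
      patient_id = sprintf("%s_P%02d", ct_label, patient),
      lineage = lineages[match(subtype, labels)],
      subtype = subtype,
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(rbind, blocks)
  cell_meta <- do.call(rbind, meta)
  rownames(counts) <- cell_meta$cell_id
  colnames(counts) <- gene_ids
  expression_atlas(counts, gene_ids, cell_meta, planted_genes = planted)
}

#' Construct and validate an ExpressionAtlas
#'
#' @param counts Cells-x-genes matrix of non-negative integer counts
#'   (dense or sparse; stored sparse).
#' @param gene_ids Unique gene identifiers, one per column.
#' @param cell_meta Data.frame with columns cell_id, cancer_type,
#'   patient_id, lineage, subtype; one row per count-matrix row.
#' @param planted_genes Optional identifiers of simulated planted genes
#'   (bookkeeping for simulation studies; empty for real data).
#' @return An `ExpressionAtlas` object.
#' @export
expression_atlas <- function(counts, gene_ids = colnames(counts), cell_meta,
                             planted_genes = character(0)) {
  required <- c("cell_id", "cancer_type", "patient_id", "lineage", "subtype")
  assert_that(is.data.frame(cell_meta) && all(required %in% names(cell_meta)),
              paste("cell_meta must contain columns:",
                    paste(required, collapse = ", ")))
  assert_that(nrow(cell_meta) == nrow(counts),
              "cell_meta must have one row per cell (count-matrix row)")
  assert_that(length(gene_ids) == ncol(counts),
              "gene_ids length must equal the number of count columns")
  assert_that(!anyDuplicated(gene_ids), "gene_ids must be unique")
  assert_that(!anyDuplicated(cell_meta$cell_id), "cell_ids must be unique")
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.vector(counts)
  assert_that(all(vals >= 0) && all(vals == floor(vals)),
              "counts must be non-negative integers")
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  rownames(counts) <- cell_meta$cell_id
  colnames(counts) <- gene_ids
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 cell_meta = cell_meta,
                 planted_genes = as.character(planted_genes)),
            class = "ExpressionAtlas")
}

#' @export
print.ExpressionAtlas <- function(x, ...) {
  cat(sprintf("ExpressionAtlas: %d cells x %d genes, %d cancer type(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cancer_type))))
  tab <- table(x$cell_meta$lineage)
  cat("  lineages:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(x$planted_genes)) {
    cat("  planted genes:", paste(x$planted_genes, collapse = ", "), "\n")
  }
  invisible(x)
}
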