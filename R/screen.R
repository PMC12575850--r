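#' Configuration for the end-to-end screen
#'
#' Collects the inputs and thresholds of [run_screen()]. Thresholds
#' default to the screen's standard settings: adjusted-p cutoff 0.05, at
#' least 100 exhausted CD8+ cells per cancer type, gene universe backed by
#' at least 2 sources, specificity breadth threshold at 10% of the
#' maximum TPM.
#'
#' @param atlas An [expression_atlas()], or a directory containing files
#'   written by [write_atlas()].
#' @param gene_sets Optional [gene_set_collection()] (or GMT path) of
#'   source gene lists; when given, the tested universe is
#'   [assemble_multi_source()] of these sources intersected with the atlas
#'   genes. When `NULL`, all atlas genes are tested.
#' @param tpm Optional genes-x-cell-types TPM matrix (or TSV path) for the
#'   specificity join; needs `tcell_column`.
#' @param tcell_column T-cell column of `tpm`.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param min_exhausted Minimum exhausted cells per retained cancer type
#'   (default 100).
#' @param min_sources Minimum sources per universe gene (default 2).
#' @param specificity_frac Breadth threshold fraction (default 0.10).
#' @param corr_scope `"pooled"` or `"per_cancer_median"`.
#' @param exhausted_labels Subtype labels merged as exhausted.
#' @param require_max_universality Filter candidates to maximal
#'   universality (default TRUE).
#' @param eps Fold-change pseudocount.
#' @param seed Integer seed recorded in the manifest (the screen itself is
#'   deterministic given its inputs).
#' @param out_dir Optional output directory for per-stage TSV artifacts
#'   and the JSON run manifest.
#' @return A `RunConfig` list.
#' @export
run_config <- function(atlas, gene_sets = NULL, tpm = NULL,
                       tcell_column = NULL, alpha = 0.05,
                       min_exhausted = 100L, min_sources = 2L,
                       specificity_frac = 0.10,
                       corr_scope = c("pooled", "per_cancer_median"),
                       exhausted_labels = EXHAUSTED_SUBTYPES,
                       require_max_universality = TRUE,
                       eps = 1e-9, seed = 1L, out_dir = NULL) {
  corr_scope <- match.arg(corr_scope)
  assert_that(is_scalar_number(alpha) && alpha >= 0 && alpha <= 1,
              "alpha must lie in [0, 1]")
  assert_that(is_count(min_exhausted), "min_exhausted must be a non-negative integer")
  assert_that(is_count(min_sources) && min_sources >= 1,
              "min_sources must be a positive integer")
  assert_that(is_scalar_number(specificity_frac) &&
                specificity_frac > 0 && specificity_frac < 1,
              "specificity_frac must be in (0, 1)")
  assert_that(is_count(abs(seed)), "seed must be an integer")
  structure(list(atlas = atlas, gene_sets = gene_sets, tpm = tpm,
                 tcell_column = tcell_column, alpha = alpha,
                 min_exhausted = as.integer(min_exhausted),
                 min_sources = as.integer(min_sources),
                 specificity_frac = specificity_frac,
                 corr_scope = corr_scope,
                 exhausted_labels = exhausted_labels,
                 require_max_universality = require_max_universality,
                 eps = eps, seed = as.integer(seed), out_dir = out_dir),
            class = "RunConfig")
}

#' Load a RunConfig from a YAML file
#'
#' File-based counterpart of [run_config()]: scalar fields map directly;
#' `atlas` must be a directory of [write_atlas()] files, `gene_sets` a GMT
#' path and `tpm` a TSV path.
#'
#' @param path YAML configuration file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

resolve_inputs <- function(config) {
  atlas <- config$atlas
  if (is.character(atlas)) atlas <- read_atlas(atlas)
  assert_that(inherits(atlas, "ExpressionAtlas"),
              "config$atlas must be an ExpressionAtlas or atlas directory")
  gs <- config$gene_sets
  if (is.character(gs)) gs <- read_gmt(gs)
  tpm <- config$tpm
  if (is.character(tpm)) tpm <- read_matrix_tsv(tpm)
  list(atlas = atlas, gene_sets = gs, tpm = tpm)
}

#' Run the full candidate-gene screen
#'
#' Executes the pipeline end to end: gene-universe assembly, merging of
#' exhausted CD8+ subtypes, cancer-type filtering by exhausted-cell count,
#' per-cancer-type Wilcoxon differential expression with BH correction,
#' Fisher meta-combination with median log2FC and enrichment scores,
#' exhaustion-signature correlation with exhaustion scores for the
#' significantly upregulated genes, universality counting, and the final
#' candidate ranking (optionally joined with TPM specificity metrics).
#' The run is fully deterministic for fixed inputs; a JSON manifest
#' records the configuration fingerprint and the stage-by-stage funnel
#' (universe size, retained types, tested/significant/universal gene
#' counts).
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return A `ScreenResult` list: `universe`, `retained_types`,
#'   `de_results`, `meta`, `correlation`, `universality`, `candidates`,
#'   optional `specificity`, and `manifest`.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  assert_that(inherits(config, "RunConfig"), "config must be a RunConfig")
  inputs <- resolve_inputs(config)
  atlas <- inputs$atlas

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # 1. gene universe
  universe <- stage("genesets", {
    if (is.null(inputs$gene_sets)) {
      sort(atlas$gene_ids)
    } else {
      intersect(assemble_multi_source(inputs$gene_sets,
                                      min_sources = config$min_sources),
                atlas$gene_ids)
    }
  })
  assert_that(length(universe) > 0, "empty gene universe after assembly")

  # 2. group assignment and cancer-type filter
  assignment <- stage("merge_exhausted",
                      merge_exhausted(atlas$cell_meta, config$exhausted_labels))
  retained <- stage("filter_cancer_types",
                    filter_cancer_types(atlas, assignment, config$min_exhausted))
  assert_that(length(retained) > 0,
              "no cancer type retained by the exhausted-cell filter")

  # 3. per-cancer differential expression on shared normalization
  normalized <- stage("normalize", normalize_log(atlas$counts))
  de_results <- stage("differential_expression", lapply(retained, function(ct) {
    differential_expression(atlas, ct, gene_subset = universe,
                            assignment = assignment, alpha = config$alpha,
                            eps = config$eps, normalized = normalized)
  }))
  names(de_results) <- retained

  # 4. meta-combination and enrichment scores
  meta <- stage("meta", enrichment_scores(combine_across_cancers(de_results)))

  # 5. exhaustion correlation for significantly upregulated genes
  cd8_ids <- assignment$cell_id[
    atlas$cell_meta$cancer_type[match(assignment$cell_id,
                                      atlas$cell_meta$cell_id)] %in% retained]
  norm_cd8 <- normalized[cd8_ids, , drop = FALSE]
  gated <- meta$gene_id[meta$combined_p_adj < config$alpha &
                          meta$median_log2fc > 0]
  corr <- stage("exhaustion_correlation", {
    if (length(gated) == 0) {
      warning("no significantly upregulated genes; correlation table empty")
      empty <- data.frame(gene_id = character(0), r = numeric(0),
                          p = numeric(0), p_adj = numeric(0),
                          exhaustion_rank = integer(0),
                          exhaustion_score = numeric(0))
      class(empty) <- c("ExhaustionCorrelationTable", "data.frame")
      empty
    } else {
      ct_of <- atlas$cell_meta$cancer_type[match(cd8_ids, atlas$cell_meta$cell_id)]
      exhaustion_correlation(norm_cd8, gated,
                             signature = exhaustion_signature(norm_cd8),
                             scope = config$corr_scope, cancer_type = ct_of)
    }
  })

  # 6. universality and final ranking
  uni <- stage("universality", universality(de_results, alpha = config$alpha))
  candidates <- stage("prioritize",
                      prioritize(meta, corr, uni,
                                 config$require_max_universality))

  # 7. optional specificity join
  spec <- NULL
  if (!is.null(inputs$tpm)) {
    spec <- stage("specificity",
                  specificity_profile(inputs$tpm,
                                      tcell_column = config$tcell_column %||%
                                        attr(inputs$tpm, "tcell_column"),
                                      frac = config$specificity_frac))
    idx <- match(candidates$gene_id, spec$gene_id)
    candidates$breadth <- spec$breadth[idx]
    candidates$tcell_rank <- spec$tcell_rank[idx]
    candidates$tcell_ratio <- spec$tcell_ratio[idx]
  }

  config_json <- jsonlite::toJSON(list(
    alpha = config$alpha, min_exhausted = config$min_exhausted,
    min_sources = config$min_sources, corr_scope = config$corr_scope,
    specificity_frac = config$specificity_frac,
    require_max_universality = config$require_max_universality,
    eps = config$eps, seed = config$seed,
    exhausted_labels = config$exhausted_labels), auto_unbox = TRUE)
  manifest <- list(
    package = "mitoscreen",
    version = as.character(utils::packageVersion("mitoscreen")),
    config = jsonlite::fromJSON(config_json),
    config_hash = fnv1a_hash(as.character(config_json)),
    funnel = list(
      n_cells = nrow(atlas$counts),
      n_cd8_cells = nrow(assignment),
      n_exhausted_cells = sum(assignment$group == "exhausted"),
      universe_size = length(universe),
      cancer_types_total = length(unique(atlas$cell_meta$cancer_type)),
      cancer_types_retained = length(retained),
      genes_tested = nrow(meta),
      genes_significant_up = length(gated),
      genes_universal = sum(uni[meta$gene_id] == meta$k_tested &
                              meta$k_tested > 0, na.rm = TRUE),
      candidates = nrow(candidates)
    )
  )

  result <- structure(list(universe = universe, retained_types = retained,
                           de_results = de_results, meta = meta,
                           correlation = corr, universality = uni,
                           candidates = candidates, specificity = spec,
                           manifest = manifest),
                      class = "ScreenResult")
  if (!is.null(config$out_dir)) write_screen_result(result, config$out_dir)
  result
}

#' Write the per-stage artifacts of a screen run
#'
#' One TSV per cancer type of DE results, the meta/correlation/candidate
#' tables, the optional specificity profile, and the JSON manifest.
#'
#' @param result A `ScreenResult`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_screen_result <- function(result, dir) {
  assert_that(inherits(result, "ScreenResult"), "result must be a ScreenResult")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_list(result$universe, file.path(dir, "universe.txt"))
  for (ct in names(result$de_results)) {
    tab <- result$de_results[[ct]]$table
    write_tsv(tab[, c("gene_id", "log2fc", "p", "p_adj", "n_exhausted",
                      "n_other")],
              file.path(dir, sprintf("de_%s.tsv", ct)))
  }
  write_tsv(result$meta, file.path(dir, "meta_gene_table.tsv"))
  write_tsv(result$correlation, file.path(dir, "exhaustion_correlation.tsv"))
  write_tsv(result$candidates, file.path(dir, "candidates.tsv"))
  if (!is.null(result$specificity)) {
    write_tsv(result$specificity, file.path(dir, "specificity.tsv"))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.ScreenResult <- function(x, ...) {
  f <- x$manifest$funnel
  cat("ScreenResult\n")
  cat(sprintf("  cells: %d (%d CD8+, %d exhausted)\n", f$n_cells,
              f$n_cd8_cells, f$n_exhausted_cells))
  cat(sprintf("  universe: %d genes; cancer types retained: %d/%d\n",
              f$universe_size, f$cancer_types_retained,
              f$cancer_types_total))
  cat(sprintf("  significant up: %d; universal: %d; candidates: %d\n",
              f$genes_significant_up, f$genes_universal, f$candidates))
  if (nrow(x$candidates) > 0) {
    cat("  top candidates:",
        paste(utils::head(x$candidates$gene_id, 5), collapse = ", "), "\n")
  }
  invisible(x)
}
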