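# Shared fixture builders for the simulation-based tests.

small_params <- function(seed = 1L, ...) {
  defaults <- list(
    n_cancer_types = 2L, patients_per_type = 2L, cells_per_patient = 120L,
    n_genes = 60L, n_planted = 1L, planted_log2fc = 2, marker_log2fc = 2,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(atlas_sim_params, args)
}

# subtype mix used when a test needs many exhausted cells per type
tex_heavy_props <- c("terminal Tex" = 0.15, "GZMK+ Tex" = 0.10,
                     "TCF7+ Tex" = 0.10, "OXPHOX- Tex" = 0.05,
                     "CD8 Tem" = 0.20, "CD8 Tn" = 0.20, "CD4 Tconv" = 0.20)

# three overlapping synthetic source lists whose 2-of-3 assembly is exactly
# the non-marker genes of an atlas (the checkpoint markers are not
# mitochondria-related, so the screened universe excludes them)
mito_style_sources <- function(atlas) {
  genes <- setdiff(atlas$gene_ids, EXHAUSTION_MARKERS)
  gene_set_collection(list(
    sourceA = genes,
    sourceB = genes,
    sourceC = genes[seq_len(min(10, length(genes)))]
  ))
}
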