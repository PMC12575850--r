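---
title: "Methods: the mitoscreen candidate-gene screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mitoscreen candidate-gene screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

## The screening problem

Tumor-infiltrating CD8⁺ T cells progressively lose effector function — a
state called exhaustion — and mitochondrial metabolism is a suspected
driver of that transition. `mitoscreen` implements a pan-cancer screen
that asks, for a universe of mitochondria-related genes: which genes are
consistently upregulated in exhausted CD8⁺ T cells across cancer types,
and how strongly does each track the canonical exhaustion program?

The substrate is a single-cell atlas of T cells annotated with cancer
type, patient, lineage and subtype, where four exhausted CD8⁺ subtypes
are distinguished: `GZMK+ Tex`, `TCF7+ Tex`, `OXPHOX- Tex` and
`terminal Tex`. These are merged into one "exhausted" group; all other
CD8⁺ cells form the comparison group, and non-CD8 cells are excluded.

## The screen, stage by stage

1. **Gene universe.** Mitochondria-related genes are assembled from
   several exported source lists (e.g. MitoCarta, MitoProteome, the AmiGO
   mitochondrion annotation); a gene enters the universe when at least
   `min_sources = 2` sources contain it. The rule, not any particular
   resulting count, is the contract — the size depends on database
   versions. Identifiers are bare symbols, case-sensitive, with optional
   case folding or a user-supplied alias table.
2. **Cancer-type filter.** Cancer types with fewer than 100 exhausted
   CD8⁺ cells are removed; a type with exactly 100 is retained.
3. **Differential expression.** Per retained cancer type, each universe
   gene is tested between exhausted and other CD8⁺ cells with a
   two-sided Wilcoxon rank-sum test on log-normalized expression
   (`ln(1 + 10^4 · count / library_size)`), BH-adjusted over exactly the
   tested gene set. The log2 fold change is the difference of
   log2-transformed group means with a pseudocount `eps = 1e-9`, computed
   on normalized values by default (raw counts optionally).
4. **Meta-combination.** Per gene, raw p-values are combined across the
   cancer types where the gene was tested by Fisher's method
   (`X² = −2Σ ln p` against chi-square with `2k` df; zeros are clamped to
   1e-300 because `ln 0` is undefined), the median log2FC is taken across
   types, and the combined p-values are BH-adjusted over all genes.
5. **Enrichment score.** Genes are ranked by descending median log2FC
   (ties broken by smaller combined p, then gene id) and the rank is
   normalized to `(n − rank + 1)/n ∈ (0, 1]`, so larger means more
   enriched.
6. **Exhaustion score.** For the genes significantly upregulated at the
   meta level (combined BH p < 0.05 and median log2FC > 0), the Pearson
   correlation between the gene's normalized expression and the
   exhaustion signature — the per-cell mean normalized expression of
   PDCD1, CTLA4, HAVCR2, LAG3 and TOX — is computed across the pooled
   CD8⁺ cells of retained cancer types, with a t-transform p-value and
   BH adjustment. The descending correlation rank is normalized the same
   way.
7. **Universality.** The number of cancer types in which the gene is
   significantly upregulated (per-type BH p < 0.05 and log2FC > 0).
8. **Final ranking.** Candidates are filtered to maximal universality
   (significant upregulation in every tested type; the filter is a flag)
   and ordered by descending `enrichment_score + exhaustion_score`, ties
   by combined p.

### Conventions the source method leaves open

Several details are conventions we fixed and record here and in output
metadata: score direction (larger = stronger candidate, normalized rank
in `(0,1]`); the exhaustion-score ordering key (the correlation
coefficient itself, not its adjusted p); the gate for the correlation
step (meta-level significance rather than per-type, with per-type
gating available via configuration); the correlation scope (pooled CD8⁺
cells by default, median of per-cancer correlations as an option); and
the additive combination of the two rank scores for the final order. The
"upregulated" call is `p_adj < 0.05` **and** `log2FC > 0`. The Wilcoxon
statistic is the default rank-based test behind single-cell
`FindMarkers`-style DE; BH is used for adjustment throughout.

## Companion analyses

**Expression specificity.** Given a genes × cell-types TPM table (81
cell types in the Human Protein Atlas-style consensus), each gene gets:
its *breadth* — the number of cell types whose TPM strictly exceeds 10%
of the gene's maximum ("exceeded" is read strictly); its *T-cell rank* —
descending rank of the T-cell TPM, minimum rank on ties; and its
*T-cell ratio* — T-cell TPM over the median TPM of the *other* cell
types (the T-cell entry is excluded from the median; a positive value
over a zero median is `Inf`, 0/0 is 0 with a flag). All three are
invariant to positive rescaling of the row.

**Tumor vs. normal pathway dysregulation.** Tumor and normal bulk
cohorts (emulating merged TCGA/GTEx pairs) are merged and
quantile-normalized — the classic rank-mean algorithm, via
`limma::normalizeQuantiles` — to remove cohort-level technical shifts;
each gene then gets a two-sided Wilcoxon test and BH adjustment. A
pathway's score is, by default, the mean log2FC of its significant DEGs;
variants (mean over all members; signed significant fraction) share the
same machinery. Significance comes from a permutation null: `B = 1000`
same-size gene sets drawn without replacement from the tested universe.
Because the default score exists only when a set contains at least one
significant member, null draws without one are excluded rather than
scored zero — conditioning the null on the same event keeps the p-value
valid when significance is sparse (with scores of 0 for such draws the
p-value is anti-conservative, which we observed directly in null
simulations). Permutation p-values are bounded below by `1/(B+1)` and
never zero. Counts of dysregulated pathways use BH within condition;
score matrices are z-scaled per pathway across conditions (sample SD;
zero-variance rows become zero and are flagged).

**Assay formulas.** Killing efficiency
`[1 − (TC_e/beads_e)/(TC_c/beads_c)] × 100%` (negative values are
reported, not clipped — clipping is a presentation choice);
bead-normalized proliferation `cells/beads`; caliper tumor volume
`V = 0.5·a·b²` with the humane endpoint flagged at 1500 mm³ (axes
swapped with a warning if given minor-first); and linear least-squares
standard-curve calibration with flagged extrapolation — a colorimetric
kit in its linear range, so a 4PL fit is deliberately out of scope.

## The synthetic atlas generator

All pipeline stages are exercised on seeded generators rather than
downloads. The count model is negative binomial with mean
`library_size_mean · s_c · r_g` where `s_c` is a lognormal per-cell
factor (sdlog 0.3) times a lognormal per-patient offset (sdlog 0.2),
and `r_g` is a gamma-distributed (shape 0.7) relative abundance
normalized to sum to one — a standard overdispersed scRNA noise model
that assumes the least about what rank-based DE exploits. The dispersion
default is 0.5 (variance `μ + 0.5μ²`). Planted candidate genes and the
five markers have their means multiplied by `2^log2fc` in exhausted
cells of every cancer type; both default to log2FC 2. Marker and planted
genes are floored at the median relative abundance, reflecting that the
real checkpoint markers are robustly detected in CD8⁺ T cells; a
candidate planted at near-zero expression would be undetectable by any
method and uninformative as a test. One child random stream is derived
per cancer type from the root seed, so generation is reproducible under
subsetting.

Default composition: 15% terminal Tex, 10% GZMK⁺ Tex, 10% TCF7⁺ Tex, 5%
OXPHOX⁻ Tex, 40% non-exhausted CD8 and 20% CD4 cells (to exercise
lineage exclusion), 12 cancer types × 4 patients × 250 cells, 500 genes,
library size 2000 counts per cell for that panel size.

The generator deliberately does **not** emulate doublets, ambient RNA,
batch structure, per-cancer cell-count imbalance, or gene–gene
correlation beyond the planted effects. Passing tests therefore
demonstrate that the pipeline's statistics are correct and calibrated
under a clean generative model — not that the screen's biological
conclusions transfer to any particular real atlas.

The TPM generator plants T-cell-exclusive genes (positive TPM only in
the T-cell column), one ubiquitous control (high, even expression), and
lognormal background. The bulk-cohort generator draws lognormal
expression with shared per-gene baselines, adds configured log2 shifts
to tumor means of shifted pathways (accumulating for genes in several),
and can apply a tumor-wide batch factor so quantile normalization has
real work to do.

## Numerical choices

* Exact Wilcoxon enumerates the permutation distribution of the
  rank-sum (pooled n ≤ 12); the two-sided p is
  `P(|W − E[W]| ≥ |w − E[W]|)`, symmetric-safe under ties. The normal
  mode uses the tie-corrected variance with a continuity correction and
  underflows to `.Machine$double.xmin` rather than 0; an all-tied gene
  returns p = 1 and log2FC 0.
* BH is `stats::p.adjust(method = "BH")` behind the package's validated
  surface; an independent step-up implementation serves as the test
  oracle.
* Zero-variance genes get `NA` correlation and are excluded from the
  exhaustion ranking; genes without an exhaustion score contribute 0 to
  the final ordering and survive only when the universality filter is
  off.
* Tie-breaks everywhere are deterministic (smaller p, then
  lexicographic gene id), so reruns are byte-identical; the run manifest
  records a configuration fingerprint and the stage funnel.

## Problem sizes used by the test suite

The suite verifies calibration and recovery at sizes chosen to make the
statistical claims sharp while remaining desk-scale: exact-oracle
enumeration over all splits of n ≤ 10; 10,000 random vectors for the BH
oracle; a 10,000-gene single-type null atlas for the p < 0.05 fraction;
50 three-type null atlases (150 genes each) for combined-p uniformity;
20 replicates of the reference simulation (12 cancer types, 500 genes,
one planted gene at log2FC 2, ≥ 300 cells per group per type) for
planted recovery; 500 null simulations at B = 1000 for permutation
validity. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* The pathway score follows a documented default rather than a unique
  published formula; all variants share the permutation machinery, and
  the significant-member mean is only informative where significance is
  widespread in the tested universe.
* The generator's planted effects are homogeneous across cancer types;
  heterogeneous effect sizes (present in real atlases) would lower
  universality and are not modeled.
* Pearson correlation on sparse log-normalized expression is driven by
  the expressed fraction; the per-cancer-median scope mitigates, but
  does not remove, pooling artifacts across cancer types.
* No pseudobulk or mixed-model DE: cells are treated as exchangeable
  within cancer type, as the rank-sum test assumes.
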