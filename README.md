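# imcscope

Single-cell analysis of multiplexed imaging mass cytometry (IMC) data,
built around the immune microenvironment of chronic liver-allograft
rejection, and validated end to end on a ground-truth synthetic tissue
simulator.

IMC ablates a stained tissue section in ~1 µm spots and quantifies
heavy-metal-tagged antibodies by mass spectrometry, producing one raw
ion-count image channel per marker. Given such multi-channel ROI stacks
(here: 8 immune markers — CD20, CD68, CD66a, CD45, CD45RA, CD3, CD8, HLADR —
plus collagen-1 and an iridium nuclear stain), the package answers three
questions a transplant-immunology study asks of rejecting (CR) versus
non-rejecting (NR) liver tissue: *which* immune subpopulations are present,
*how they arrange themselves in space*, and *whether per-ROI summaries
separate the cohorts*.

## What it implements

- **Synthetic tissue simulator** (`simulate_roi`, `generate_cohort`):
  non-overlapping disk cells with lognormal-Poisson channel rendering,
  NR-like sparse immune fields vs CR-like immune aggregates with planted
  pairwise spatial attractions, and a full ground truth (mask, phenotypes,
  expression draws) as the oracle for every downstream stage.
- **Segmentation** (`segment_roi` and friends): hot-pixel removal (5× the
  3×3 median), 2× upscaling, three-class pixel classification (multiscale
  features + seeded random forest, trained from sparse label images),
  watershed nuclei on the distance transform, bounded cell expansion, 1×
  rescaling, and per-cell measurement of mean raw intensities.
- **Phenotyping** (`phenograph_cluster`, `profile_clusters`,
  `annotate_immune`, `tsne_embed`): Phenograph meta-clustering — exact kNN
  (k = 75) on raw intensities, Jaccard edge reweighting, seeded Louvain —
  cluster×marker median profiles with column-standardized z-scores
  (z = (m − mean)/SD per marker across clusters, population SD), rule-based
  immune annotation, and a seeded exact tSNE (perplexity 30).
- **Quantification** (`median_marker_per_roi`, `immune_proportions`,
  `standardize_counts`, `compare_cohorts`): per-ROI medians and immune
  proportions (immune-cell denominator), count z-scores across ROIs, and
  Wilcoxon rank-sum cohort tests (exact for n ≤ 10 without ties) with BH
  q-values.
- **Spatial neighborhood analysis** (`build_neighbor_graph`,
  `permutation_test`, `summarize_cohort`): neighbors are cells whose masks
  come within 4 px (4 µm); for every ordered phenotype pair (a, b) the
  statistic is the mean count of b-neighbors per a-cell, tested by two
  one-tailed label-permutation tests with the +1 estimator
  `p = (1 + #{perm ≥ obs})/(n_perm + 1)` over matched permutation streams
  (study settings: 99 permutations at α 0.05 over all cells, or 5000 at
  α 0.01 over immune cells); cohort scores are
  100 × (interactions − avoidances)/testable ROIs.
- **Cohort modeling** (`pca_fit`, `pc1_test`, `logistic_pc1`,
  `correlation_network`): scaled PCA with deterministic signs and
  per-variable contributions, Wilcoxon on PC1 by cohort, logistic regression
  of P(CR) on PC1 with a ridge fallback under complete separation, and a
  Spearman marker correlation network.
- **Pipeline** (`run_pipeline`, `validate_config`): one-call orchestration
  of all stages from a YAML/list config with a single master seed, per-stage
  manifests, and reproducible outputs.

## Worked example

Simulate one chronic-rejection ROI (which plants an attraction: 80% of
CTL-2 cells are placed adjacent to a Macrophage-2 cell) and test that pair
spatially on the ground-truth mask:

```r
library(imcscope)
sim <- simulate_roi(tissue_sim_config("CR", seed = 11))
length(sim$truth$phenotype_of_cell)        # 420 cells, 200 immune

g   <- build_neighbor_graph(sim$truth$true_mask, radius_px = 4)
res <- permutation_test(g, sim$truth$phenotype_of_cell,
                        phenotypes = names(default_mix("CR")),
                        n_perm = 5000, alpha = 0.01,
                        permutable = sim$truth$phenotype_of_cell != "not immune cell",
                        seed = 1)
subset(res, pheno_a == "Macrophage-2" & pheno_b == "CTL-2")
#  observed_stat     p_high p_low     verdict
#      0.6808511 0.00019996     1 interaction
```

Each Macrophage-2 cell has on average 0.68 CTL-2 neighbors within 4 µm; none
of 5000 label permutations reached the observed statistic, so the pair is
called a significant interaction (p ≈ 2e-4 < 0.01) — the planted structure
is recovered. The numbered scripts under `analysis/` run the same logic as a
full workflow (simulate 8 NR / 24 CR ROIs → segment → cluster → quantify →
neighborhood → model), printing, among other things, per-ROI segmentation
recall, the meta-cluster table, cohort-shifted subpopulations, the strongest
CR interactions, and the PC1 separation (on a desk-scale run: PC1 carried
59.6% of the variance, Wilcoxon p = 3.2e-05, and all 32 ROIs were modeled at
correct-class probability ≥ 0.75).

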