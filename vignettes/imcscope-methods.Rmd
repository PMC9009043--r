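---
title: "Methods: simulation-validated single-cell IMC analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-validated single-cell IMC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Imaging mass cytometry (IMC) ablates a stained tissue section pixel by pixel
(~1 µm spots) and quantifies heavy-metal-tagged antibodies by mass
spectrometry, yielding one raw ion-count channel per marker. In chronic
liver-allograft rejection, the question is which immune subpopulations
infiltrate the graft, how they arrange themselves in space, and whether
per-ROI summaries of those populations separate rejecting (CR) from
non-rejecting (NR) tissue. `imcscope` implements the full analysis chain —
segmentation, meta-clustering, per-ROI quantification, spatial neighborhood
testing, and cohort modeling — and pairs it with a ground-truth tissue
simulator so that every stage can be tested against known answers. Clinical
IMC images are not redistributable; the simulator is therefore the package's
test bed, and its role and limits are spelled out below.

# The synthetic tissue simulator

`simulate_roi()` draws non-overlapping disk cells (radius ~ N(r, 10% r),
clipped at 2 px, placed by rejection sampling with a ≥ 1 px gap so the true
mask doubles as an unambiguous segmentation oracle). The default panel is 10
channels: 8 immune markers (CD20, CD68, CD66a, CD45, CD45RA, CD3, CD8,
HLADR), collagen-1 as a structural channel, and an iridium nuclear
intercalator. Twelve phenotype profiles are bundled — the 11 immune
subpopulations observed in chronic rejection plus a hepatocyte background
profile expressing none of the immune markers. Paired populations of the same
identity (CTL-1/CTL-2, Macrophage-1/2, Other T-cell-1/2) differ by signal
intensity, mirroring the way graph clustering splits marker-positive
populations by brightness in real data.

Rendering follows an overdispersed count model: each cell draws one lognormal
expression level per marker (CV 0.25 by default), every pixel of the cell
then draws a Poisson count at that rate, on top of a Poisson(0.2) background.
The nuclear channel concentrates 85% of its rate in an inner nuclear disk
(45% of the cell radius, floor 1.5 px) with a 15% cytoplasmic halo — this is
what makes the three pixel classes (nuclear / cytoplasm–membrane /
background) learnable. Collagen is a smooth, cell-independent sinusoidal
ridge field; it carries morphology but no cell identity, and that is why it
is excluded from the immune-annotation marker set even though it participates
in clustering. Isolated detector hot pixels (rate 1e-4, +Poisson(80)) are
sprinkled in so the hot-pixel filter has real work to do.

Cohort geometry encodes the two study conditions. NR: immune cells from a
homogeneous spatial point process, at a density of ~40 immune cells per
desk-scale ROI, with a mix dominated by neutrophils and unspecified CD45+
leukocytes and no Macrophage-1 (a population unique to rejection). CR: ~200
immune cells concentrated in Gaussian aggregates (~4 per desk ROI, SD 25 px,
the count scaling with ROI area), enriched for Macrophage-2, CTL-2 and the
two unspecified T-cell populations, plus a planted spatial attraction: 80% of
CTL-2 cells are placed with a 1–3 px boundary gap to a random Macrophage-2
cell. The cohort default is 8 NR / 24 CR ROIs. Where the source material
states a quantity (panel composition, cohort shape, clustering and
neighborhood parameters, ~1 mm² ROIs at 1 µm/px) the simulator uses it; the
per-phenotype abundance mixes are the package's own choice, picked once to
match the qualitative orderings (which populations are enriched where) and
not revisited.

Two scales exist: the desk scale (300 × 300 px) used throughout the tests,
and the full scale (1000 × 1000 px, cell counts scaled by area) behind
`scale = "full"`. The desk scale keeps a full pipeline run on one CPU in
minutes; the methods are scale-free, and the one place where scale matters
statistically (permutation-test calibration, below) uses 600 × 600 ROIs.

What the simulator does **not** emulate: channel spillover, tissue
autofluorescence, ablation artifacts, cell-shape irregularity (liver cells
are morphologically uniform, but disks are still an idealization), touching
cells (the ≥ 1 px gap means segmentation tests measure the pipeline's
recovery of resolvable cells, not its behavior under contact), and any 3D
structure. Passing tests therefore demonstrate correctness of the
computations and recoverability under realistic noise — not performance on
degraded clinical material.

# Segmentation

The chain is: hot-pixel removal → 2× bilinear upscaling → three-class pixel
classification → nuclei watershed → cell expansion → 1× rescaling →
measurement.

* **Hot pixels.** A pixel exceeding `factor` × (3×3 neighborhood median,
  edges replicated) is replaced by that median; the default factor is 5, the
  common IMC convention. With sparse Poisson backgrounds the local median is
  usually 0, so the filter also flattens isolated background counts to 0 —
  a consequence of the rule worth knowing: after filtering, the per-ROI
  medians of markers expressed by few cells sit at exactly 0, and the
  modeling stage drops such constant columns (with a log message) before
  PCA.
* **Pixel classifier.** Interactive brush training is replaced by sparse
  label images; in simulated runs those labels are sampled from the ground
  truth (`training_labels_from_truth()`, 2000 px/class). Features are
  per-channel Gaussian smoothings (σ = 1, 2, 4), gradient magnitude and
  Laplacian of the σ = 1 smoothing; the classifier is a seeded random forest
  (60 trees, ≤ 3000 training pixels per class). Held-out pixel accuracy on
  synthetic data is ≥ 0.9 (tested).
* **Nuclei and cells.** Nuclei are connected components of
  `nuclear ≥ 0.5`, split by a watershed on the distance transform (seed
  separation 3 px at 2×), with components under 4 px dropped. Cells are
  nuclei expanded outward up to 5 px (2×) through pixels where the
  background posterior is < 0.5, each pixel assigned to the nearest nucleus
  pixel (exact Euclidean, offsets visited in increasing distance), ties to
  the lower label for determinism.
* **Measurement.** Per cell at 1×: pixel area, centroid (0-based, mean of
  pixel coordinates) and per-marker **mean** intensity over the cell's
  pixels, computed on the hot-pixel-filtered raw counts, never transformed.
  Cluster profiles later use the **median** over cells; the two statistics
  are deliberately distinct and each stated where used.
* **Neighbor graph.** Cells are neighbors iff their masks come within
  4 px (= 4 µm) Euclidean distance — dilation semantics, not centroid
  distance — implemented by exact offset enumeration and verified against a
  brute-force minimum boundary distance on small instances.

# Meta-clustering and annotation

`phenograph_cluster()` is the Phenograph construction: exact k-nearest
neighbors (k = 75) on the raw per-cell mean intensities of all panel
markers, candidate edges reweighted by the Jaccard overlap of the two
neighbor sets, zero-overlap edges dropped, and seeded Louvain modularity
maximization; cluster ids are ordered by decreasing size. Exact kNN (no
approximate index) is affordable at desk scale and removes a source of
nondeterminism.

Two behaviors of this construction matter for interpretation. First,
modularity maximization sub-splits sparse kNN graphs: on two well-separated
Gaussian blobs with k much smaller than the blob size, the optimal-modularity
partition has *more* than two communities (each nested inside one blob).
The package's tests assert exact blob recovery when k is comparable to the
blob size and purity (refinement of the truth) when it is not. Second,
because clustering runs on raw intensities, a marker-positive population
with a long brightness tail can split into two clusters of the same identity
— which is precisely why the study's phenotypes carry -1/-2 suffixes, and
why the labeling rule numbers those families by size.

`profile_clusters()` builds the cluster × marker matrix of median per-cell
intensities plus its column-standardized z matrix (per marker across
clusters, population SD, zero-SD columns to 0) — the heatmap convention.
`annotate_immune()` calls a cluster immune iff its standardized median
exceeds 1.0 for at least one immune-role marker, but standardizes `log1p`
medians for this call: on the raw scale, an intensity split of one
CD68-positive population into two or three clusters inflates the column SD
until the dimmest genuinely positive cluster falls below any fixed
threshold, whereas on the log scale positivity is an order-of-magnitude
property and survives such splits. The heatmap z stays on the raw scale.
Labels then follow the marker-pattern rules (positivity at z ≥ 0.5 on the
same standardized scale): CD20 → B-cell; CD68 → Macrophage; CD3 with CD8 →
CTL; CD3 without CD8 → Other T-cell; CD45RA → Naive T-cell; CD66a →
Neutrophil; HLADR → HLADR+; CD45 alone → Other Leukocyte. CTL, Macrophage
and Other T-cell are always numbered by decreasing size; other labels are
numbered only when duplicated. Non-immune clusters collapse to
`"not immune cell"`. CD45 positivity is deliberately *not* required for the
T-cell rules: not every T- or B-cell population is strongly CD45+ in IMC.

`tsne_embed()` is an exact-gradient tSNE (perplexity 30, with bisection for
the conditional precisions, early exaggeration 12 for 100 iterations,
adaptive gains, 500 iterations): no tSNE package exists in the supported R
environment, and at the package's working scale (≤ a few thousand cells,
subsampled in the workflow script) the O(n²) exact gradient is both
affordable and the θ → 0 limit of the Barnes-Hut approximation. The `theta`
and `initial_dims` arguments are recorded in the output attributes for
provenance and are otherwise inert (110 initial dimensions is a no-op for a
10-marker panel). The embedding is visualization only; nothing downstream
consumes it.

# Quantification

Per ROI: the median marker signal over **all** cells; immune subpopulation
counts and their proportions of the ROI's immune cells (non-immune cells
excluded from the denominator; ROIs with zero immune cells get missing
proportions, not zeros); and within-subpopulation z-scores of counts across
ROIs (population SD). Cohort comparisons use the two-sided Wilcoxon rank-sum
test: the exact null when both groups have ≤ 10 observations and no ties,
the tie-corrected normal approximation otherwise. Raw p-values are the
headline (the study convention); Benjamini–Hochberg q-values are always
reported alongside. ROIs are treated as independent observations — a known
simplification when patients contribute 1–2 ROIs each; the package does not
attempt mixed-effects modeling of patient-level correlation.

Two distinct percentage conventions coexist in cohort composition summaries
and are computed side by side by `composition_summary()`: a cohort's share
of all immune cells (CR: 27,908 / 30,646 = 91.1%) and a cohort's
within-cohort immune fraction (NR: 2,738 / 16,454 = 16.6%). The published
16.6% only reconciles with the second convention, so both are always
labeled explicitly rather than guessing intent.

# Neighborhood permutation testing

For every ordered phenotype pair (a, b), the statistic is the mean number of
b-phenotype neighbors per a-phenotype cell (a = b allowed; a cell is never
its own neighbor; undefined when a is absent). The null fixes the graph and
uniformly permutes the labels over the permutable cells; all pairs share one
matched permutation stream per ROI. Two one-tailed p-values use the +1
pseudo-count estimator `p = (1 + #{perm ≥ obs}) / (n_perm + 1)` (and ≤ for
the low tail), which can never return 0 and is super-uniform under the null.
Verdicts at α: interaction if `p_high < α`, avoidance if `p_low < α`. The
two analysis modes are exposed through `permutable`: all cells (the
29-cluster screening run at 99 permutations, α 0.05) or immune cells only
(the focused run at 5000 permutations, α 0.01). No multiple-testing
correction is applied across the 121 pairs by default, matching the per-pair
thresholds convention of the source analyses. Cohort aggregation gives each
pair 100 × (interactions − avoidances) / testable ROIs, so one positive and
one negative verdict cancel.

Calibration deserves care because the statistic is an integer count. The
estimator's granularity caps the one-tailed null rejection rate at
⌈α(M+1)⌉−1)/(M+1) (0.049 at M = 999, α = 0.05), and ties at the rejection
threshold subtract up to the tie mass, which scales like 1/σ of the count.
The package's calibration experiments therefore run on dense 600 × 600 null
ROIs (~1,700 cells), where the count statistic is effectively continuous and
the pooled one-tailed rejection rate lands at ~0.045, within two
replicate-level binomial standard errors of α for 200 null ROIs. On sparse
desk-scale graphs the same tests are validly conservative — the unit suite
asserts super-uniformity there rather than exact calibration. The
Monte-Carlo estimator itself is validated against exhaustive enumeration of
all label permutations on ≤ 7-cell graphs.

# Cohort modeling

`pca_fit()` centers and (by default) scales columns to unit variance before
the eigendecomposition — markers differ widely in raw signal intensity, so
unscaled PCA would be dominated by the brightest channel; an unscaled mode
exists. Loadings carry a deterministic sign convention (largest-magnitude
loading positive), variable contributions are squared loadings normalized to
100% per component, and reconstruction with all components reproduces the
processed matrix to < 1e-8 (tested). PC1 is compared between cohorts with
the same Wilcoxon engine as quantification, then fed to a logistic
regression of P(CR). With 8-vs-24 designs and strong effects the cohorts
frequently separate completely, where the unpenalized MLE does not exist;
the fit detects separation directly (disjoint score ranges, or divergent or
non-finite coefficients) and refits with a ridge penalty of 1.0 on the
slope, flagging the model. Reported outputs are per-ROI probabilities, the
count of ROIs at correct-class probability ≥ 0.75, and outliers (< 0.5).
The marker correlation network defaults to Spearman (robust to the
heavy-tailed raw intensities; the coefficient is configurable) with edges at
|r| ≥ 0.8; constant columns produce missing correlations, not edges.

The modeling-recovery experiments (20 replicate 8 NR / 24 CR cohorts) run on
`simulate_marker_features()`, a feature-level companion simulator that draws
per-ROI median marker signals with a planted two-fold CR elevation on the
immune markers over lognormal ROI noise (SD 0.4 on the log scale). The
criterion under test concerns the modeling module's behavior given per-ROI
features; generating 640 full images would multiply runtime without changing
what is tested. The image pipeline's own end-to-end behavior is covered once
per suite by the workflow tests.

# Numerical and design choices, in one place

* Coordinates are 0-based (row, col) pixel centers; mask label 0 is
  background; labels are compacted to 1..K.
* All z-scores use the population SD (denominator n); zero-SD columns give
  z = 0.
* Watershed and expansion tie-breaks go to the lower label; cluster ids,
  phenotype numbering and edge orderings are all deterministic given the
  seed, and every stochastic stage takes an explicit seed derived from one
  master seed (`derive_seed`).
* Even-length medians are the mean of the middle two values.
* TIFF round trips: integer data ≤ 65535 is stored as 16-bit and
  round-trips bit-identically; larger labels use 32-bit storage (exact below
  2²⁴); cell-table CSVs round-trip below 1e-9.
* Problem sizes in the shipped tests and acceptance script: desk-scale
  300 × 300 ROIs (≈ 340–420 cells), 10-ROI balanced cohorts (≈ 3,900 cells)
  for clustering recovery, 600 × 600 ROIs for calibration, 200 null
  replicates, 5000-permutation planted-recovery runs on 10 CR ROIs, and
  20 replicate modeling cohorts. These are the package's chosen working
  sizes; all scale up by configuration.

# Known limitations

The simulator's idealizations (listed above) bound what the test suite can
certify. The immune-call threshold (z ≥ 1 on log-scale standardized
medians) is a declared substitute for an unstated manual criterion, exposed
as a parameter. Phenotype labels follow size-rank numbering, so a label such
as "CTL-1" names the larger CTL cluster in *this* dataset, not a fixed
biological identity across datasets. ROIs are treated as exchangeable;
patient-level random effects are out of scope. The tSNE implementation is
exact rather than Barnes-Hut and is intended for subsampled visualization,
not full-cohort embedding.
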