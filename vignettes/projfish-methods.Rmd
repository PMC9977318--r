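---
title: "Methods: multimodal cell typing and projection mapping with projfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal cell typing and projection mapping with projfish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis problem

Multiplexed FISH experiments on thick brain sections measure, for every
segmented neuron, (i) spot counts for a panel of marker genes, (ii) a 3D
soma centroid and morphology descriptors, and (iii) mean fluorescence
intensities of several retrograde tracer channels, each injected into a
different axonal target region. `projfish` turns these measurements into
three annotations per neuron — a molecular cluster, an anatomical
subregion, and a set of projection targets — and quantifies how well
marker-gene expression alone predicts the projection class. A reference
single-cell RNA-seq experiment anchors the molecular clusters and drives
the selection of the marker-gene panel in the first place.

# Reference clustering

Reference counts pass standard QC (genes detected in ≥ 5 cells; cells
bounded by detected genes, mitochondrial fraction < 0.055 and UMI total
< 2×10⁵). `qc_filter()` iterates the gene and cell filters to a fixed
point: removing cells can push genes below the detection floor and vice
versa, and iterating makes the operation idempotent, which one pass does
not guarantee.

`normalize_scale()` total-count normalizes (to 10⁴), applies `log1p`,
keeps the top 5,000 genes by standardized variance around a quadratic
mean–variance trend, regresses each gene on UMI total and mitochondrial
fraction, and z-scores the residuals. Clustering runs on the top 40 PCs:
a k-nearest-neighbour graph (Euclidean, k = 25) is re-weighted by the
Jaccard overlap of neighbour sets (a point's set is itself plus its k
neighbours; edges below 1/15 are pruned) and partitioned by Louvain
modularity optimization at resolution 1.5. All randomness is controlled
by an explicit seed; identical inputs and seed give identical labels.

Cluster quality is assessed three ways: per-cell silhouettes in PC space;
bootstrap stability (`bootstrap_stability()` reclusters 100 random 80%
subsamples and records, per original cluster, the best Jaccard match
among new clusters, restricted to subsampled cells); and a dendrogram
over cluster centroids (complete linkage by default — the linkage is a
free choice and is exposed as an argument). Marker genes come from
one-vs-rest Wilcoxon rank-sum tests restricted to genes with natural-log
fold change ≥ 0.75 and expressing fraction ≥ 0.25 in at least one group,
Bonferroni-corrected over all genes.

# Marker-panel selection

Candidates must pass adjusted p ≤ 0.05 and logFC ≥ 0.55 and are ranked by
binarity (`pct.1 − pct.2`). `greedy_panel()` grows the panel by accuracy:
at each step it adds the candidate that maximizes the fraction of
reference cells re-assigned to their own cluster by Pearson correlation
against cluster mean profiles. Because a correlation needs at least two
genes, the first step selects the best *pair* by exhaustive search; this
is the smallest valid panel and the natural initialization. Ties are
broken lexicographically by gene identifier, so the procedure is
deterministic. Self-mapping intentionally uses each cell's own profile
against leave-nothing-out cluster means; the accuracy curve is recorded
as produced and is not forced to be monotone.

**Numerical note.** On a two-gene panel the Pearson correlation of a cell
with every centroid is analytically ±1, so the argmax is decided entirely
by ties. `assign_by_correlation()` rounds correlations to 10⁻⁹ before the
argmax so that analytically tied values compare equal and the documented
tie rule (lowest cluster index) actually applies, rather than float
noise. Cells with zero variance over the gene subset are flagged
unassignable and count as errors in accuracy.

# FISH typing

Spot counts are z-scored per gene **without** a log transform: spot
detection has a roughly constant false-positive floor, and logging would
inflate the weight of those false positives. A cell is "positive" for a
gene when its count strictly exceeds 10 — the average background spot
load per cell per gene measured in tissue lacking the probed gene.
Clustering is two-pass: a coarse pass (k = 25, resolution 0.2) isolates
non-neurons, which are removed when a cluster has median soma volume
below 600 µm³ *and* neuronal-marker positive fraction below 20% (the
criterion is principled; the two cutoffs are package defaults, as only
the criterion is standard); a fine pass (k = 45, resolution 1.0) defines
molecular clusters, relabeled so cluster 1 has the highest cluster-mean
total spot count. FISH clusters map to reference clusters by the same
correlation assignment over the shared panel, summarized as a
correspondence-fraction matrix. Morphology contrasts (cluster vs rest)
report the rank-sum p (Bonferroni over clusters × features), Cohen's d on
the pooled SD, and the rank-biserial correlation r_g = 1 − 2U/(n₁n₂);
a contrast is "reportable" only with corrected p below α and at least a
medium effect (|d| > 0.5 or |r_g| > 0.28).

# Projection calls

Tracer intensities are z-scored per channel (population SD by default;
the convention is configurable and irrelevant to thresholding, which is
scale-equivariant). For each channel, `youden_threshold()` sweeps
candidate cuts at midpoints between consecutive sorted unique values of a
labeled calibration subset and returns the threshold maximizing
J = sensitivity + specificity − 1, taking the lowest threshold on ties.
In the field this calibration set comes from manual inspection of sampled
neurons; here it is an explicit input (simulation truth or a user
annotation file), which makes the step reproducible. A cell's projection
set is every channel strictly above its threshold; 0/1/≥2 targets give
the unlabeled/single/collateral categories.

# Spatial parcellation

Per-gene expression images are reconstructed on a regular grid as
Gaussian-kernel-weighted averages of cell z-scores (default bandwidth
25 µm; the reconstruction kernel is not standardized in the field, and
the bandwidth trades spatial detail against shot noise). PCA with voxels
as observations and genes as variables yields eigen images; genes are
ranked by mean |loading| over the top PCs and the top three drive the
parcellation. Cells are classified per gene by Otsu's threshold (256-bin
histogram, between-class variance maximization, positive at or above the
threshold, applied to raw spot counts by default with z-scores as an
option), and the per-gene sign tuple maps to a named subregion through a
configuration table. A Gaussian-process classifier (RBF kernel, length
scale 1.0 after rescaling coordinates to unit variance so the scale is
meaningful for any tissue size; one-vs-rest with renormalized
probabilities, since the multiclass treatment is a free choice) converts
cell classes into a probabilistic map; the mask thresholds probability at
0.5, and each cell inherits the subregion at its centroid. Exact GP cost
grows cubically, so training is capped at 2,000 subsampled cells with a
fixed seed, and the desk-scale grid default is 10–25 µm with 1 µm
available by configuration. Parcellation is applied independently per
sample.

# Predicting projections from expression

Collateral cells (about 1% of neurons) are excluded; remaining cells are
labeled with their single target or "unlabeled", optionally merging the
hindbrain targets (PBN, PCRt, vlPAG) into one class. One L2-penalized
logistic model per class is fitted with observation weights inversely
proportional to multiclass frequencies; the ridge strength is chosen per
training fold by internal 3-fold CV over a logarithmic grid of 10 values
(or fixed by configuration). Scores use 20 randomized repeats of
stratified 5-fold CV by default: one-vs-rest AUC per class and macro f1
per repeat, averaged; the confusion matrix pools repeats and is
row-normalized (TP over class size). The permutation test shuffles the
whole label vector (class frequencies preserved; unlabeled cells are an
ordinary class) and reports p = (1 + #{null ≥ observed})/(1 + N).
Recursive feature elimination removes, per class, the feature with the
smallest standardized coefficient magnitude and records the
cross-validated AUC at every panel size; rank 1 is the last survivor.

# What the synthetic data emulates

`sim_config()` fixes the study conditions: 13 clusters and 1,500
reference cells; a 2,500 × 4,000 × 100 µm slab with two axis-aligned
spatial domains whose per-cluster density weights (0.9/0.1) make them
molecularly distinct; near-binary marker programs (negative binomial
"on" counts, mean 50, size 4, around a Poisson background of 10
spots/cell/gene); five tracer channels with lognormal background
(meanlog log 100, sdlog 0.4) plus an additive labeled signal of 400,
labeling efficiency 0.78 and a 1% collateral rate; per-cluster soma
morphology (one large-soma cluster at 2,506 µm³-scale mean, others
around 1,500 µm³); and a 15% non-neuron population with small somata
(300 µm³) and background-only counts. Non-neurons draw background at a
lower rate (3 spots/cell/gene) because background spot load scales with
soma volume; this is also what makes the non-neuron removal criterion
testable at the >10 threshold. Background spots are Poisson — the field
reports a single mean rate, not a dispersion — and tracer signal is
additive on the linear intensity scale because mean-ROI extraction is
linear. Tracer intensity distributions are not reported anywhere we
could anchor them; the lognormal background is an explicit assumption.

The generator does **not** emulate image-level effects (PSFs, spectral
crosstalk, segmentation errors), anatomical curvature of real
boundaries, continuous expression gradients, or batch effects between
samples. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative assumptions, not robustness to
every artifact of real tissue.

# Problem sizes and numerical choices

The test-suite and acceptance computations run at desk scale, chosen as
the package's own verification sizes: 1,500 reference cells for
clustering recovery (10 seeds), 10,000 cells for projection-recovery and
background-rate calibration, 5,000 cells at a 10 µm grid for GP
parcellation, 50 × 50 permutation runs for null calibration of the
permutation test. Other conventions: z-scoring uses the population SD
for tracer channels and the sample SD for expression (both exposed);
zero-variance channels raise errors naming the channel; Otsu refuses
constant input; Youden requires both calibration classes; bootstrap
Jaccard is NA for clusters absent from a subsample; degenerate
single-gene panels are rejected (correlation undefined).

# Limitations

Greedy panel selection is locally optimal only; cross-validated panel
generalization is out of scope. The GP segmentation is exact and
therefore subsampled rather than sparse/inducing-point based. Doublet
detection beyond threshold filters, batch integration across datasets,
and atlas registration are not provided. Cluster merging ("confusing
clusters") is exposed as an explicit manual operation with the criteria
left to the analyst, since no quantitative merge rule is standard.
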