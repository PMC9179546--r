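---
title: "Integrative multi-omics portrayal: models, parameters and design choices"
author: "combisom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative multi-omics portrayal: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combisom)
```

## The model

`combisom` treats each gene as a point in a joint omics space. For matched
gene-by-sample matrices of log expression (Gex), promoter methylation score
(Dme) and gene-centric copy-number score (CNV), preprocessing is:

1. **Centralization** — subtract each gene's cohort mean, giving delta
   scores Δe, Δm, Δc that express deviation from the cohort average. A
   consequence worth keeping in mind is *aliasing*: an effect confined to
   one sample group necessarily appears with opposite sign, scaled by the
   group's cohort fraction, in all other groups.
2. **Harmonization** — divide each modality by its global standard
   deviation over all entries. This is the simplest transform that makes
   the three numeric scales comparable and it is testable by a global-SD
   invariant; it deliberately does not touch within-modality gene-level
   scale differences (quantile normalization and friends are out of scope).
3. **Weighted combination** — concatenate the three sample-length profiles
   into one vector with block *b* multiplied by weight *w<sub>b</sub>*,
   under *w<sub>e</sub> + w<sub>m</sub> + w<sub>c</sub>* = 1. Linear
   weight scaling was chosen over square-root scaling because it makes the
   decomposition an exact inverse; the squared weights govern the distance
   contribution of each layer. The representation is recorded in the model
   so an alternative scaling could be added without breaking persistence.

A self-organizing map is then trained on the combined vectors. Each map
unit's weight vector is a **metagene**: a prototype profile over samples
with the same three-block layout. Dividing block *b* by *w<sub>b</sub>*
recovers per-modality metagene matrices; a modality trained with weight 0
carries no information and decomposes to `NA`.

### Weight presets

| preset | w_e | w_m | w_c | use |
|---|---|---|---|---|
| balanced (default) | 1/3 | 1/3 | 1/3 | balanced couplings between the layers |
| gex-/dme-/cnv-dominant | 0.99 | 0.005 | 0.005 | effectively single-ome topology |
| gex-dme-bivariant | 0.5 | 0.5 | 0 | two-layer co-variance landscape |

The dominant presets put 0.99 on one layer and split the remaining 0.01
equally, which is the only way to combine a 0.99 main weight with the
sum-to-one constraint.

## SOM training

Training is batch Kohonen with a Gaussian neighbourhood on a quadratic grid
(default side 45; the examples and tests use 20 to keep runtimes in
seconds). The schedule has two phases — ordering (radius `grid_side/2` → 3
over 20 epochs) and fine-tuning (3 → 0.7 over 30 epochs) — with linear
radius decay. Initialization spans the lattice linearly over the first two
principal components of the combined profiles, which makes training fully
deterministic; the seed is recorded for any future stochastic scheme and
for the seeded network layouts downstream.

The final radius ends *below one grid unit*: with a Gaussian kernel of
width 1 a direct neighbour still receives 61% of the central weight, which
blends unit prototypes across module borders; since spot detection cuts at
90% of the portrait extreme, that blending systematically clips boundary
units out of spots. At 0.7 the neighbour weight drops to 36%, letting
boundary units specialize while retaining mild topological coupling.

Ties in best-matching-unit search are broken toward the lowest unit index,
everywhere, for determinism. Unit index *u* (1-based) sits at row
`(u-1) %/% side + 1`, column `(u-1) %% side + 1`, row 1 at the top.

## Derived maps

- **Portraits**: grid renderings of one sample's (or group mean's)
  decomposed metagene scores. All modalities share the grid, so cells and
  genes correspond across layers.
- **Variance maps** use the metagene-level cross-sample variance
  (denominator S−1). Metagene level was chosen over gene level because the
  supporting maps operate on the trained grid; the population map carries
  the gene-density information separately.
- **ScoV** (signed square-root covariance): for a sample pair of portraits,
  sign(a·b)·√|a·b| — the single-sample analogue of a covariance on
  centralized data; for a group, sign(c)·√|c| of the true cross-sample
  covariance. One consistent definition serves both per-sample panels and
  group panels; the square root compresses dynamic range without moving
  zero or reordering magnitudes.
- **Spot modules**: cells above `threshold_fraction` (default 0.9, "90% of
  maximum") of a group portrait's extreme, split into 8-connected
  components (diagonals connect — SOM textures are smooth, so diagonal
  adjacency is natural), discarding components under 3 cells. The summary
  map runs detection at both signs on every group portrait of every
  modality and merges components that share cells (union-find over
  overlaps, not blind mask union, which would merge merely adjacent
  distinct modules). Both signs are thresholded against the portrait's
  *absolute* extreme, so the weak side of a one-sided portrait — whose
  extreme is noise — contributes no detections. Labels A, B, … follow the
  clockwise angular order of spot centroids around the grid centre,
  starting at the top-left diagonal, making labels reproducible.
- **GSZ**: per sample, `(mean_members − mean_all) / (sd_all / √n_members)`
  — the standard normalized set mean against the all-gene background. The
  variance-shrinkage elaborations found in enrichment literature are out of
  scope; the plain z form is oracle-testable. Ternary coordinates divide
  the three |GSZ| values into percentages with signs kept as tags, since
  percentages must be non-negative and the treatment of negative scores is
  otherwise unspecified.
- **Prognostic maps**: per metagene, samples above the unit profile's
  mean + 1 SD form the "high" arm; a univariate Cox fit of high vs rest
  gives HR = exp(β). High-vs-rest was chosen over high-vs-cohort-average as
  the well-posed two-arm contrast. Units whose high arm is smaller than
  `min_group` (default 5) or lacks events are `NA`, guarding against
  unstable small-arm fits. Cox machinery is delegated to the `survival`
  package; the bespoke part is the dichotomization and map assembly.
- **Similarity networks**: Pearson correlation between flattened metagene
  portraits (matching "heatmaps of the portraits", not gene space), top-k
  neighbour edges (k = 3) with ties broken by sample order, seeded
  Fruchterman–Reingold layout. Cluster-vs-annotation agreement uses
  average-linkage clustering of 1−r distances cut at the number of
  annotated groups, scored by the adjusted Rand index.

## The synthetic cohort

`default_cohort()` generates 2000 genes × 120 samples in three groups
emulating the canonical lower-grade-glioma strata:

| group | n | planted structure | hazard |
|---|---|---|---|
| IDHwt-like | 30 | Chr7-like gained segment (150 genes), Chr10-like lost segment (150); low methylation | 3.0 |
| IDHA-like | 50 | strongest repressive hyper-methylation module shift (1.2, 100 genes), intermediate broad methylation gradient (0.35), pure-expression TF-driven module (0.9, 100 genes) | 1.0 |
| IDHO-like | 40 | two co-deleted segments (220 genes total, one shared profile), highest methylation gradient (0.7), repressive shift 1.1 | 1.0 |

Couplings: expression follows copy number with slope γ = 0.7 and the
repressive methylation shift with slope β = −0.8; the methylation gradient
is a background process over non-module genes with per-gene loadings
U(0, 0.5). Noise is Gaussian (SD 0.35/0.3/0.25 for Gex/Dme/CNV — typical
array-scale values); 10% of each group's samples are "low-purity" with all
group effects attenuated by α = 0.4, emulating samples of reduced tumour
cell content. Survival is exponential (baseline rate 1/60 per month) with
uniform administrative censoring in 48–120 months.

These defaults were fixed by a design analysis of group-portrait effect
sizes *before* the test suite was frozen: because of centralization
aliasing, every group portrait contains echoes of every group-specific
module, and the 90% spot threshold isolates one module per detection only
if the runner-up stays below ~80% of the portrait extreme. The chosen
amplitudes satisfy that margin for all nine group portraits. Two further
consequences of that analysis:

- **Susceptibility spread.** Module genes carry a per-gene effect
  multiplier, by default U(0.95, 1.05). Narrow homogeneity is what makes
  planted modules recoverable through a sharp 90% threshold (the SOM sorts
  any amplitude gradient spatially, and the threshold then clips the sorted
  low end); wide heterogeneity (e.g. U(0.5, 1.5)) is what makes per-gene
  cross-omics scatter plots informative. The two regimes are genuinely
  incompatible in one setting, so the spread is a configuration parameter:
  recovery tests use the narrow default, the scatter-correlation test a
  wide dedicated cohort.
- **What passing tests do and do not show.** The generator emulates
  group-level block structure, monotone couplings, a global gradient,
  attenuated low-purity samples and exponential survival. It does not
  emulate beta-value marginals of methylation arrays, segment-boundary
  noise in CNV calls, probe-level measurement models, nor continuous
  (non-group) biological gradients. Recovery of planted modules therefore
  validates the machinery — preprocessing, training, decomposition,
  thresholding, statistics — not the method's resolution limits on real
  tumour data.

## Numerical choices and degenerate inputs

- Missing matrix cells are imputed with the gene-row mean at read time
  (SOM distance needs complete vectors; the imputation preserves the exact
  zero row mean after centralization); all-missing rows are dropped with a
  warning.
- A modality with zero global SD harmonizes to all-zeros with a warning
  rather than an error, so degenerate layers flow through as inert blocks.
- Portraits whose positive (negative) side is empty yield no over- (under-)
  spots, with a warning from `detect_spots` and silent skipping in the
  summary map.
- All assignment ties resolve to the lowest unit index; sample rankings
  break score ties by sample id; network neighbour ties break by sample
  order.
- Model persistence uses an RDS container; the round trip is bit-exact.

## Problem sizes

Examples, tests and the acceptance script run the default cohort
(2000 × 120) on a 20 × 20 grid — about four seconds of training — and the
hazard-recovery study over 20 regenerated cohorts in about a minute. The
45 × 45 default grid matches the scale used for real cohorts of a few
hundred samples and trains in well under a minute on one core.

## Known limitations

- Harmonization equalizes global scales only; strong modality-internal
  heteroscedasticity will still tilt the combined distances.
- Spot labels are reproducible but not stable across retraining with
  different seeds or grids (the map orientation is arbitrary under the
  PCA-sign convention).
- The per-sample ScoV portrait is a single-sample product surrogate, not an
  estimator of a per-sample covariance; only the group ScoV has a
  covariance interpretation.
- The prognostic maps fit univariate, unadjusted models; they rank
  metagenes, they do not replace multivariate survival modelling.
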