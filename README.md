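# combisom

Integrative portrayal of matched gene expression (Gex), DNA promoter
methylation (Dme) and copy-number (CNV) data with a single self-organizing
map (SOM).

## The problem and the method

Multi-omics studies of tumour cohorts produce three gene-by-sample score
matrices measured on the same patients. Analysing each layer separately
obscures the couplings that drive the biology: promoter methylation
*represses* expression, while copy-number changes push expression through a
*dose–response* relationship. `combisom` trains **one** SOM on per-gene
vectors that concatenate the three layers so that every gene occupies the
same position in all three landscapes.

Per gene *g*, each modality score is centralized
(Δ<sub>gs</sub> = x<sub>gs</sub> − x̄<sub>g·</sub>), harmonized by the
modality's global standard deviation, and the three sample-length profiles
are concatenated with weights *w<sub>e</sub> + w<sub>m</sub> + w<sub>c</sub> = 1*:

    v_g = [ w_e · Δe_g , w_m · Δm_g , w_c · Δc_g ]

Euclidean distances between combined vectors then decompose as
√(Σ<sub>b</sub> w<sub>b</sub>² d<sub>b</sub>²), so the weights set each
layer's influence on the map topology. Balanced weights (1/3, 1/3, 1/3) are
the default; "dominant" presets (0.99 on one layer) give effectively
single-ome maps, and (0.5, 0.5, 0) drops a layer entirely. After batch
training on a 45 × 45 grid (Gaussian neighbourhood, two-phase radius decay,
PCA lattice initialization), unit vectors are decomposed back into
per-modality **metagene** matrices, yielding mutually aligned per-sample
*portraits*.

Downstream maps all live on this shared grid:

- **Variance maps** (cross-sample metagene variance) and **population maps**
  (genes per unit).
- **ScoV maps** — signed square-root covariance, sign(c)·√|c|, between two
  layers' metagene profiles; negative cells mark repressive Gex·Dme
  coupling, positive cells CNV dose–response.
- **Spot modules** — 8-connected regions above 90% of a group portrait's
  extreme score, merged across groups and layers, labelled A, B, …
  clockwise; each spot carries its genes and triple-omics profiles.
- **Gene-set Z scores** (GSZ) per sample and modality, with ternary
  Gex/Dme/CNV compositions and signature maps.
- **Prognostic maps** — per metagene, a Cox proportional-hazards ratio of
  samples whose score exceeds mean + 1 SD versus the rest.
- **Cohort similarity** — portrait correlation heatmaps, top-k similarity
  networks and cluster-vs-annotation agreement.

A configurable synthetic-cohort generator plants arm-level CNV segments with
expression dose–response, a repressive methylation module, a global
methylation gradient, a pure-expression module, low-purity samples and
group-dependent survival hazards — with full ground truth, so the entire
pipeline is testable offline.

## Worked example

```r
library(combisom)

sim <- default_cohort(seed = 7)          # 2000 genes x 120 samples, 3 groups
ds  <- sim$dataset
ds  <- multiomics_dataset(centralize(ds$gex), centralize(ds$dme),
                          centralize(ds$cnv), ds$annotations, ds$gene_sets)
ds  <- harmonize(ds)
model <- train_som(combine_modalities(ds, "balanced"), grid_side = 20, seed = 7)
model
#> <som_model> 20x20 grid, 2000 genes, 120 samples, weights 0.333/0.333/0.333
#>   quantization error: init=5.539, phase1=5.323, phase2=5.060

dec  <- decompose_model(model)
gp   <- group_portraits(model, dec, ds$annotations)
summ <- spot_summary_map(model, dec, gp)
sapply(summ$spots, function(s) c(s$label, s$sign, s$dominant_modality,
                                 length(s$member_genes)))
#>      [,1]    [,2]   [,3]    [,4]   [,5]
#> [1,] "A"     "B"    "C"     "D"    "E"
#> [2,] "under" "over" "under" "over" "under"
#> [3,] "Dme"   "CNV"  "CNV"   "Gex"  "CNV"
#> [4,] "100"   "130"  "214"   "86"   "142"
```

Five spots recover the five planted modules: A is the repressive
methylation module (hyper-methylated, hence expression-"under" elsewhere),
B the gained segment, C the co-deleted pair, D the pure-expression module
and E the lost segment. The planted hazard (multiplier 3 in the IDHwt-like
group) is recovered at the gained segment:

```r
units <- sort(unique(model$assignment[sim$truth$modules$gain]))
sp <- structure(list(member_units = units), class = "spot_module")
spot_hr(sp, dec, ds$annotations)[1, ]
#>   modality       hr   ci_low  ci_high n_high            p
#> 1      Gex 2.769677 1.722067 4.454593     27 2.649042e-05
```

The 27 high-expression samples are IDHwt-like tumours (3 of the group's 30
are low-purity and fall below the mean + 1 SD cut); the Cox interval
comfortably covers the planted hazard ratio of 3.

`run_pipeline()` chains the whole workflow (simulate/ingest → preprocess →
train → portraits → ScoV → spots → gene sets → prognosis → similarity) and
writes every numeric map as TSV plus a reproducibility manifest; a thin CLI
lives at `inst/cli/combisom` (`simulate`, `run`, `demo`).

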