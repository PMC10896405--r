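# shapecomp

Estimating total and regional body composition from 3D optical body scans.

Dual X-ray absorptiometry (DXA) is the reference method for measuring fat
and lean masses, but it is expensive and uses ionizing radiation. A 3D
optical (3DO) surface scan is cheap and safe, and the external shape of the
body carries a strong signal about its internal composition. `shapecomp` is
an R package for researchers studying that mapping: it implements the full
pipeline from topology-standardized body meshes to ten DXA-style composition
variables (total/trunk/arm/leg fat and lean masses, visceral fat mass,
percent body fat), with a deliberately paired design — every linear
component has a nonlinear counterpart — so the contribution of each modeling
choice can be ablated.

## What is inside

* **Mesh core** — OBJ/PLY I/O (ascii and binary little-endian), the
  per-vertex Euclidean MAE reconstruction metric, and deterministic
  multi-level graph hierarchies for mesh convolution
  (`readMesh`, `vertexMAE`, `buildHierarchy`).
* **Registration** — simplified topology standardization: per-vertex affine
  nonrigid deformation of a template toward a scan (alternating
  nearest-neighbor correspondence and sparse least squares, monotone energy)
  plus a sparse nearest-neighbor transfer matrix
  (`nonrigidRegister`, `nearestNeighborMatrix`).
* **Shape models** — a linear PCA shape space over flattened vertex
  coordinates (`fitPCAShape`) and a graph convolutional autoencoder with
  spatially varying kernels,
  `y_i = b + Σ_{j∈N(i)} (Σ_m A_ijm B_m) x_j`,
  trained with a pretrain/finetune schedule and analytic gradients
  (`newMeshAutoencoder`, `trainAutoencoder`). Both expose
  `shapeEncode` / `shapeDecode`.
* **Regression heads** — minimum-norm OLS and Gaussian process regression
  with the squared dot-product kernel `k(x,z) = (σ₀² + x·z)²` (equivalent to
  Bayesian degree-2 polynomial regression), sex-stratified, with
  `[height, weight, age]` appended to the shape features
  (`fitOLS`, `fitGPR`, `fitStratified`, `layerSearch`).
* **Evaluation** — accuracy (RMSE, RMSE normalized to the fully linear
  PCA+OLS baseline, R²) and test–retest precision (Glüer-style %CV and
  repeat RMSE over same-day duplicate scans) across controlled model
  permutations (`runAblation`, `withholdExperiment`).
* **Synthetic cohorts** — a seeded generator producing the study-design
  roles (pose-varied pretraining identities, multi-identity finetuning,
  evaluation, duplicate-scan test) with monotone-quadratic shape→composition
  ground truth (`synthConfig`, `generateCohort`).

Cohorts are `ShapeCohort` objects extending `SummarizedExperiment`: the
`coords` assay holds one flattened mesh per scan, `colData` the demographics,
targets and split membership.

## Worked example

Generate a synthetic cohort, fit the linear shape model at a parameter count
matched to the training size, and compare model permutations:

```r
library(shapecomp)

cfg <- synthConfig(seed = 42, nFinetune = 300, nEval = 0, nTest = 80,
                   nPretrainIdentities = 0)
cohort <- generateCohort(cfg)
pca <- fitPCAShape(cohortMeshes(cohort, split = "finetune"), d = 150)
res <- runAblation(cohort, pca)

subset(res$accuracy, target == "total_fat" & metric == "rmse")
#>       permutation    sex    target metric     value
#>  Baseline_HWA_GPR female total_fat   rmse 5.1821716
#>  Baseline_HWA_GPR   male total_fat   rmse 7.8332669
#>           PCA_OLS female total_fat   rmse 2.1033324
#>           PCA_OLS   male total_fat   rmse 4.5816781
#>           PCA_GPR female total_fat   rmse 1.0180823
#>           PCA_GPR   male total_fat   rmse 0.9557866
#>          Mesh_GPR female total_fat   rmse 0.9766924
#>          Mesh_GPR   male total_fat   rmse 0.9434925

prec <- subset(res$precision, target == "visceral_fat" & metric == "cv_percent")
aggregate(value ~ permutation, prec, mean)
#>        permutation     value
#> 1 Baseline_HWA_GPR  0.000000
#> 2         Mesh_GPR  1.120571
#> 3          PCA_GPR  1.332949
#> 4          PCA_OLS 15.059596
```

Reading the output: total-fat RMSE (kg, against the cohort's reference
values) drops from the demographics-only baseline (5.2–7.8 kg) to the linear
PCA+OLS pipeline (2.1–4.6 kg) to the nonlinear GPR head (≈1 kg, near the
0.5 kg injected reference noise). The precision table shows visceral-fat
test–retest %CV over duplicate scans: the interpolating high-dimensional OLS
amplifies scan noise (15% CV) while GPR stays near 1.3%; the baseline is 0 by
construction since demographics do not change between same-day scans.

A thin command-line wrapper over the same functions ships in
`inst/scripts/shapecomp` (subcommands `synth`, `register`, `fit-pca`,
`train-ae`, `regress`, `ablate`, `withhold`; global `--seed`, `--out`,
`--force`):

```sh
Rscript inst/scripts/shapecomp synth --seed 7 --finetune 60 --eval 10 --test 20 --out cohort/
Rscript inst/scripts/shapecomp ablate --cohort cohort/ --dim 30 --out ablation/
```

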