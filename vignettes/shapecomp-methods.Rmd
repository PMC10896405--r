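---
title: "Estimating body composition from 3D body shape: models and methods"
author: "shapecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating body composition from 3D body shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapecomp)
```

## The problem

Total and regional body composition — fat and lean masses of the whole body,
trunk, arms and legs, visceral fat mass, and percent body fat — are normally
measured with dual X-ray absorptiometry (DXA). A 3D optical (3DO) surface scan
of the body is cheap, fast and radiation-free, and its external geometry
carries a strong signal about internal composition. `shapecomp` implements a
full pipeline from fixed-topology body meshes to ten DXA-style composition
variables, built so that every linear component has a nonlinear counterpart
and the two can be ablated against each other:

1. **Topology standardization** (`nonrigidRegister`, `nearestNeighborMatrix`):
   raw scans with arbitrary vertex layouts are mapped onto one shared
   triangulation so that vertex *i* corresponds anatomically across subjects.
2. **Shape models**: a linear PCA shape space (`fitPCAShape`) and a graph
   convolutional mesh autoencoder (`newMeshAutoencoder`, `trainAutoencoder`)
   that both expose `shapeEncode` / `shapeDecode`.
3. **Regression heads**: minimum-norm ordinary least squares (`fitOLS`) and
   Gaussian process regression with a squared dot-product kernel (`fitGPR`),
   fitted separately per sex with demographics `[height, weight, age]`
   appended to the shape features.
4. **Evaluation** (`runAblation`): accuracy as RMSE / normalized RMSE / R²
   on a held-out test set, and test–retest precision as Glüer-style %CV and
   repeat RMSE over same-day duplicate scans, across controlled model
   permutations that change exactly one pipeline component at a time.
5. **Synthetic cohorts** (`synthConfig`, `generateCohort`): a seeded generator
   with the statistical structure the pipeline assumes, so the whole system
   is testable offline.

## Registration

A scan is standardized in two steps that mirror common template-fitting
practice. First the template is deformed toward the scan with one 3×4 affine
transform per template vertex, minimizing

$$E = w_d \sum_i \lVert T_i v_i - \mathrm{nn}_{target}(T_i v_i)\rVert^2
    + w_s \sum_{(i,j)\in edges} \lVert T_i - T_j\rVert_F^2 ,$$

a data term pulling each deformed vertex to its nearest scan vertex plus a
first-order smoothness term on neighboring transforms. The optimizer
alternates two exact block minimizations — nearest-neighbor correspondence
with transforms fixed, then one sparse linear solve for all transforms with
correspondences fixed (the three coordinate rows decouple, so it is three
solves against one Cholesky factor). Because both steps are exact, the energy
is nonincreasing; the implementation asserts this to a 1e-9 relative
tolerance (a ridge of 1e-12 times the diagonal scale keeps the normal matrix
positive definite and can shift the energy at that order). Second, a sparse
nearest-neighbor matrix `C` (one 1 per template row, ties to the lower source
index) transfers any same-shape surface onto the template topology.

Defaults `dataWeight = 1`, `smoothWeight = 1`, `nIters = 10` are package
choices: equal weighting fits translations and moderate deformations in a few
iterations on the synthetic meshes, and a larger `smoothWeight` degrades
gracefully toward a single global affine fit (a property the tests exploit as
an oracle). Landmarks, normal-compatibility gating and hole filling are out
of scope.

## The graph convolutional autoencoder

Meshes sharing a topology form a graph whose edges are the triangle edges.
The autoencoder is built on a **graph hierarchy** computed once per template
(`buildHierarchy`): at each level a greedy breadth-first cover retains a
subset of vertices — repeatedly take the lowest-index unmarked vertex and
mark everything within `stride − 1` hops — and each retained vertex receives
as its convolution support the parent vertices within `radius` hops. Both
default to 2. Retained vertices are connected at the next level when their
parent-graph distance is at most `2·stride − 1`, which preserves
connectivity; ties everywhere break by vertex index, so the hierarchy is a
pure function of the topology. Every parent vertex lands in at least one
neighborhood (enforced; requires `radius ≥ stride − 1`).

The convolution is **spatially varying**: layer weights are M shared basis
matrices $B_m$ (out×in) plus one M-vector of mixing coefficients $A_{ij\cdot}$
per (output vertex, neighbor) edge,

$$y_i = b + \sum_{j \in N(i)} \Big(\sum_m A_{ijm} B_m\Big) x_j .$$

This keeps locality like an image CNN while letting each edge learn its own
kernel. The encoder applies one full-resolution convolution
(3 → `channelPlan[1]` channels) and then one decimating convolution per
hierarchy level; the decoder mirrors it with transpose convolutions over the
same neighborhoods. The flattened (vertex-major) bottleneck map is the latent
code, of length *bottleneck vertices × f*; on a full-body 6890-vertex
template with a 7-vertex bottleneck, channel depths 7 / 43 / 90 / 612 give
latent sizes 49 / 301 / 630 / 4284. On the synthetic template the bottleneck
vertex count follows from the hierarchy, and `latentSize()` reports the
product.

Choices the architecture leaves open were resolved as follows:

* **Nonlinearity**: ELU between all layers, linear output; smooth enough for
  clean finite-difference checks and avoids dead units at small scale.
* **Optimizer**: Adam at learning rate 1e-4 (default; scaled-down runs in the
  tests use 1e-3 to 3e-3), batch size 16, gradient averaged per batch. All
  gradients are analytic; a finite-difference test pins them to 1e-4 relative
  on randomly sampled weights.
* **Initialization**: basis entries drawn with SD
  $1/\sqrt{M\,\bar{|N|}\,c_{in}}$ and unit-variance coefficients, keeping
  activations O(1); biases start at zero.
* **Input scaling**: coordinates are centered and scaled by template
  statistics stored in the model, and decoded outputs are mapped back to mm,
  so reported reconstruction errors are always in mm while training sees
  O(1) values.
* **Schedule**: a pretraining phase on the pose-varied set initializes the
  weights, then a finetuning phase on the multi-identity set; the evaluation
  split is scored after every epoch (mean per-vertex Euclidean MAE, mm) and
  the checkpoint with the lowest evaluation MAE is returned.

Reconstruction error is `vertexMAE`: the mean over vertices of the Euclidean
distance between corresponding positions. The alternative reading — mean
absolute difference over the 3N scalar coordinates — differs by a
distribution-dependent factor; the vertex-distance form matches the
"per-vertex" framing and is what a 1 mm uniform translation maps to exactly
1 mm.

## Shape features to composition: OLS and GPR

Every regression sees `[shape features ‖ height, weight, age]`, and models
are fitted independently per sex (the shape-to-composition map differs by
sex; scaling statistics never cross strata or splits). OLS uses the SVD
pseudoinverse, so the underdetermined case — thousands of shape coefficients
against a few hundred subjects — returns the minimum-norm interpolating
solution rather than failing; that regime matters because the ablation
deliberately matches the linear model's parameter count to the autoencoder's
latent size (at the default cohort, d equals the per-stratum training count).

GPR uses the squared dot-product kernel
$k(x, z) = (\sigma_0^2 + x\cdot z)^2$, i.e. Bayesian regression over degree-2
polynomials of the features — the natural class for relations assumed
nonlinear but monotone in first and second derivatives, as composition is in
girth-like shape coordinates. The posterior mean
$m(x_*) = k_*^\top (K + \alpha I)^{-1} y$ is computed per target from one
Cholesky factor. Two scale decisions matter and were made after measuring
their effect on synthetic cohorts:

* **Feature scaling** (`standardizeX`): the default is *pooled* — center
  columns, divide all of them by one pooled SD. Per-column z-scaling (still
  available as `"column"`) amplifies low-variance, noise-dominated PCA
  directions to the same kernel weight as the dominant shape modes and
  measurably destroys both accuracy and precision of the dot-product kernel;
  pooled scaling preserves the spectrum the way an unscaled scikit-learn-style
  pipeline would see it while keeping the kernel numerically O(1).
* **Kernel inhomogeneity** (`sigma0`): the default `"auto"` sets
  $\sigma_0^2$ to the mean squared norm of the scaled training features. With
  hundreds of features and $\sigma_0 = 1$, the kernel's linear term is
  negligible against $(x\cdot z)^2$ and the fit degrades to a pure quadratic;
  the scale-aware value balances the constant, linear and quadratic terms
  (the standard normalization for inhomogeneous polynomial kernels). A fixed
  numeric value and marginal-likelihood selection (3 restarts, bounds scaled
  around the auto value) remain available.

Targets are standardized during fitting and restored at prediction; the
noise jitter `alpha` defaults to 1e-2 on that scale, reflecting that the
reference measurements themselves carry noise. Radial-basis and higher-power
dot-product kernels exist behind the same interface but are not defaults; in
this model family they overfit (near-zero training error, inflated test
error).

`layerSearch` runs the stratified GPR from every autoencoder feature layer —
the full-resolution convolution (layer 0) through the bottleneck — and
reports the per-layer test RMSE and the argmin layer per sex, since the most
predictive representation need not be the coarsest one.

## Evaluation and the ablation harness

Accuracy: `rmse` in target units; `normalizedRMSE` expresses a permutation's
RMSE as a percentage of the fully linear PCA + OLS pipeline (100% = the
linear baseline); `rSquared` is the agreement form 1 − SS_res/SS_tot, not
squared correlation, so bias is penalized. Precision over same-day duplicate
pairs: `cvPercent` is the root-mean-square within-subject SD
($|m_1 - m_2|/\sqrt2$ per pair) over the grand mean of all 2n measurements,
×100 — the grand mean rather than per-subject means, a difference that is
negligible at these noise levels; `repeatRMSE` is the plain RMSE between
trial 1 and trial 2 with no $\sqrt2$ divisor (the literal reading of an
RMSE between trials; the divided variant would halve it), used for
percentage-valued targets where a %CV of a percentage is unconventional.

`runAblation` trains all permutations on identical subject-level splits —
demographics-only GPR, PCA+OLS, PCA+GPR, GPR on raw mesh coordinates, and
GPR from every autoencoder layer — and scores accuracy on test scan 1 and
precision on the duplicate pairs, with the autoencoder's precision row pinned
to its bottleneck features so linear and deep rows compare at matched
parameter counts. Subject overlap between train and test is a hard error.

## The synthetic cohort generator

The generator emulates the study-design roles the pipeline assumes, at desk
scale, from one seed:

* **Template**: a deterministic humanoid-like closed surface (elongated,
  elliptical cross-section, waist/shoulder/head profile), ~1700 mm tall,
  226 vertices at resolution 0 (up to ~3000 at higher resolutions).
* **Shape**: k = 6 standard-normal latents through smooth linear displacement
  fields (mode 1 is always girth, the axis weight correlates with) plus
  torso-concentrated **quadratic bulge modes** driven by $z_q^2$ — the planted
  nonlinearity a linear shape space cannot represent compactly, emulating
  under-modeled abdominal shape detail. Stature scaling and a sex-offset
  field add demographic shape variation (suppressible via
  `demoVariation = FALSE` for exact-recovery tests).
* **Targets**: per-sex maps $y_t = a_t + d_t\,\text{weight} + \sum_k B_{tk}
  z_k + \sum_k C_{tk}(z_k + 3)^2$ with nonnegative B, C, so first and second
  partial derivatives in every shape coordinate are nonnegative over the
  sampled range (verified on a grid by `checkMonotoneMap`). The quadratic
  terms span **all** latents deliberately: if they were confined to the
  latents whose squares are themselves mesh modes, PCA features would contain
  the nonlinearity as an ordinary linear coordinate and OLS would trivially
  match GPR, erasing the contrast the harness exists to measure. Percent fat
  is 100·total fat/weight clipped to [0, 100]; mass draws that noise pushes
  negative are rejection-resampled (counted in the record). Per-target noise
  SDs default to DXA-scale values (e.g. 0.5 kg total fat, 0.03 kg visceral
  fat, 0.8 points percent fat).
* **Demographics**: heights ~ N(178, 7) cm for males, N(164, 6.5) for
  females; BMI = 24 + 2.4 z₁ + 1.1 z₂ + noise links weight to the girth
  latents, so the height/weight/age baseline is informative but strictly
  weaker than shape — matching the intended baseline narrative; age uniform
  18–80.
* **Roles**: a few pose-varied identities for pretraining (smooth upper-body
  lean and leg-sweep angle curves across frames), single-pose finetuning and
  evaluation sets, and a test set with same-day duplicate scans (fresh vertex
  noise at `retestNoiseSD`). Defaults are 600 finetuning, 80 evaluation and
  200 test subjects (≈300 per sex in training) with 2 mm scan and retest
  noise; splits are disjoint at the subject level and finetuning subjects are
  tagged into two named partitions for withholding experiments.

What the generator does **not** emulate: realistic anthropometric covariance,
scanner-specific artifacts (holes, pose drift between duplicates beyond
i.i.d. vertex noise), measurement-device bias, or any real template topology.
Passing tests therefore demonstrate that the pipeline recovers planted
structure and reproduces the qualitative orderings under its stated
assumptions — not clinical accuracy on real scans.

## Problem sizes and what the checks show

The test suite and the acceptance script run everything at sizes chosen for
a single CPU: regression cohorts of 500–800 subjects on the 226-vertex
template, autoencoders with channel plans like (6, 8) and M = 3 trained for
tens of epochs, and 10-seed repetitions of the qualitative comparisons. At
these sizes the seeded runs reproduce: exact PCA recovery of noiseless
linear cohorts (< 1e-6 mm); GPR on true latents within 15% of the injected
target-noise floor at n = 500; GPR beating OLS in accuracy and in
test–retest precision, and shape-informed models beating the
demographics-only baseline, in ≥ 8–10 of 10 seeds; and pretraining on the
pose-varied set improving the finetuned evaluation MAE in ≥ 7 of 10 seeds.

## Known limitations

* At desk-scale training budgets the autoencoder does not reach the linear
  PCA reconstruction floor at equal latent size; the nonlinear model's
  *reconstruction* advantage in the low-d regime is therefore not asserted
  by the tests — only its feature-quality and precision behavior through the
  regression heads, and the training-direction properties (pretraining
  benefit, monotone improvement, single-mesh overfit).
* The registration module is a single-resolution simplification: one
  template resolution, nearest-vertex correspondences without normal gating,
  no landmark terms.
* GPR predictive variances are computed nowhere; only posterior means are
  used, and no calibration is attempted.
* Pose is not disentangled from identity; the pretraining role varies pose
  only in the synthetic generator's limited sense.
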