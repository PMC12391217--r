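---
title: "Reconstructing scapula surfaces from palpable skin landmarks: models and methods"
author: "scapssm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing scapula surfaces from palpable skin landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Subject-specific bone geometry is a prerequisite for musculoskeletal and
finite-element models of the shoulder, but obtaining it normally requires CT
or MRI acquisition plus segmentation. In a motion-capture laboratory the only
scapular information available is the 3D position of a handful of *skin*
landmarks — the acromial angle (AA), the root of the scapular spine (TS),
the inferior angle (AI) and the acromioclavicular joint (AC) — palpated
through soft tissue, together with basic demographics (sex, age, weight,
height). `scapssm` turns those inputs into a full subject-specific scapula
surface in three stages:

1. a PCA **statistical shape model** (SSM) built from a cohort of
   corresponded scapula meshes;
2. twelve **skin-to-bone regression models** that convert the skin-level
   landmark coordinates into estimates of the underlying bone landmark
   coordinates;
3. a **penalized landmark-fitting optimization** that selects the shape-model
   weights whose bone landmarks best match the predicted ones.

## Coordinate conventions

All mesh and landmark coordinates are millimetres; heights are metres and
weights kilograms, enforced with sanity ranges at load time (a height above
3 m is rejected as likely centimetres). BMI is always derived as
weight/height² at construction and never supplied by the user, so it cannot
disagree with its parents.

Every subject's landmarks are expressed in the scapular **body-fixed frame**
of the International Society of Biomechanics, built from the *skin*
landmarks: origin at AA, z-axis the unit vector from TS toward AA, x-axis
the unit normal of the AA–TS–AI plane oriented anteriorly, y = z × x. The
anterior sign is resolved by requiring the AC landmark (anterior/lateral on
a right scapula) to have positive x; `flip_x` overrides this when needed.
This construction forces six skin coordinates to zero — x of AA, TS and AI;
y of AA and TS; z of AA — which is why the regression stage uses only the
six free skin coordinates as predictors. Both skin and bone landmarks are
expressed in this skin-derived frame, so bone coordinates are in general all
nonzero and all twelve are modelled.

## The statistical shape model

Training shapes must be in dense point-to-point correspondence. The package
provides the standard two-stage registration: rigid iterative closest point
(`rigid_register`, closed-form Procrustes updates, optional 4-landmark
initialization, monotone cost) and a non-rigid stage
(`nonrigid_correspond`) that warps the reference template by a
thin-plate spline interpolating the four paired bone landmarks and then
iterates nearest-point projection with a screened-Laplacian smoothing of the
displacement field under a halving stiffness schedule, ending with a pure
projection so output vertices lie exactly on the target surface. With four
control points the TPS affine part reproduces any affine transform exactly,
which the tests exploit (a uniformly scaled copy is matched to within
0.1 mm). The reference shape is configurable; by default the first shape by
sorted id is used so results are deterministic.

`build_ssm` stacks the corresponded shapes as 3N-vectors, takes the mean,
and extracts principal directions and standard deviations from the SVD of
the centered data matrix. Two deliberate choices:

* **No scale normalization.** Size is biologically the dominant mode of
  scapular variation and must remain in the model for landmark-driven
  reconstruction to recover it, so no Procrustes scaling (and by default no
  extra generalized-Procrustes iteration) is applied before PCA.
* **Weights in SD units.** `synthesize(model, kappa)` returns
  mean + Σₘ κₘ σₘ φₘ, so plausible anatomy corresponds to κ ~ N(0, I) for
  every mode uniformly. This makes the reconstruction penalty (below)
  dimensionally consistent across modes.

Model quality is quantified by the three standard SSM metrics:
`compactness` (cumulative variance fraction per mode count),
`generalization` (leave-one-out projection RMSE at a given number of modes)
and `specificity` (RMSE from randomly synthesized shapes to the nearest
training shape).

## Skin-to-bone regression

For each of the 12 responses (4 bone landmarks × 3 axes, body-fixed frame)
a linear model is selected from 17 candidate predictors: the 6 free skin
coordinates, the 6 pairwise skin-landmark distances, sex (0 = female,
1 = male), age, weight, height and BMI. Predictors are deliberately left
unscaled so coefficients are interpretable in natural units.

Selection is classic stepwise regression with partial-F tests computed from
nested residual sums of squares: the best out-of-model predictor enters if
its p-value is below `p_enter = 0.05`, then in-model predictors with
p-value above `p_remove = 0.10` are pruned (worst first) until stable. The
procedure stops when neither action applies; a response whose residual sum
of squares reaches the numerical floor stops accepting predictors, and a
constant training response degenerates cleanly to its intercept.

Because a single split can over- or under-fit, each response is fitted on
`n_folds = 10` shuffle splits (70% train / 30% test at subject level;
`floor(n · 0.7)` training rows for other cohort sizes) and each fold is
scored by

s = ½ · [ (MAE_train + MAE_test)/2 + |MAE_train − MAE_test| ],

the average error magnitude plus a penalty on the train/test gap. The fold
with the lowest score supplies the selected model (ties: lower test MAE,
then lower fold id). Both MAEs are means over their own instances. The
whole selection is reproducible bit-for-bit from its seed.

## Reconstruction

Given target bone landmarks x_target (predicted by the regressions, or
digitized directly), `reconstruct` minimizes over the first M mode weights

f(κ) = ‖x_target − x(κ)‖² + Σₘ (exp(κₘ²) − 1),

where x(κ) are the model's four bone-landmark positions after a rigid
(no-scale) paired-landmark Procrustes alignment to the target. Because the
four landmarks are labeled, the closed-form paired alignment is exact; an
ICP-style nearest-point re-pairing variant is provided for comparison and
coincides with it except when landmarks nearly collide. The exponential
penalty encodes that weights are standard normal in the population: it
vanishes at the mean shape and grows sharply beyond ~2 SD, so implausible
shapes are admitted only under strong landmark evidence. The −1 offset
keeps f(0) equal to the pure landmark misfit of the mean shape.

The optimizer is global-then-local: a seeded real-coded genetic algorithm
(tournament selection, uniform crossover, Gaussian mutation, elitism;
defaults population 50, 100 generations, box bounds ±3 SD) followed by
bounded quasi-Newton refinement (`optim` L-BFGS-B with numerical
gradients) from both the GA optimum and the mean shape, keeping the best.
The refined objective never exceeds the GA value, and identical seeds give
bit-identical results. M defaults to 5 modes: with only 12 target
coordinates (minus 6 rigid degrees of freedom) few-mode fits are better
conditioned, and in our experiments additional modes changed the surface
error negligibly while increasing runtime.

A consequence of the exponential penalty worth understanding: even when the
target is generated *exactly* from known weights κ_true, the optimum is
shrunk toward zero, leaving a residual landmark misfit of roughly
κ·exp(κ²)/a per mode, where a is that mode's landmark displacement per SD
(millimetres). Modes that barely move the four landmarks are therefore
reconstructed conservatively — this is the intended bias of the objective,
not an optimizer failure, and it dominates the landmark-to-landmark errors
reported by the test suite (sub-millimetre to a few millimetres depending
on the mode spectrum).

## Evaluation metrics

* **L2L** — per-landmark Euclidean distance between the aligned
  reconstructed bone landmarks and the target, reported per landmark.
  Its squared sum equals the objective's data term exactly.
* **S2S** — per-vertex RMSE between the reconstructed and ground-truth
  shapes over all corresponding vertices, after rigid no-scale Procrustes
  alignment (scale is kept so size errors remain visible; set
  `align = FALSE` for shapes already co-registered). Per-vertex distances
  are returned for heat-map export onto PLY.
* **Kruskal–Wallis comparison** — two-group rank test of whether the error
  distributions from digitized vs predicted landmarks differ, at α = 0.05.
  For small samples (≤ 20000 group assignments) the p-value is the exact
  permutation probability — the two-group statistic is monotone in one
  group's rank sum, so enumeration is cheap and removes the known
  inaccuracy of the chi-square approximation at such sizes; larger samples
  use the chi-square reference, whose size we measured at ≈0.06 at n = 20
  per group.

## The synthetic population

Real cohorts of segmented scapulae with paired bone/skin landmarks are
access-controlled, so the package ships a generator
(`population_config` + `generate_cohort`) that emulates the *structure* of
such a cohort with exact ground truth. What it does:

* a procedural **template**: a flattened, tapered, ridge-and-bump deformed
  geodesic sphere at an exact vertex count (default 6000) with four
  well-separated labeled vertices standing in for AA, TS, AI, AC;
* five smooth orthonormal **modes** (uniform scaling, height, bending,
  thickness, a local lateral-region change) with per-vertex RMS amplitudes
  of 4, 2.5, 1.5, 1.0 and 0.6 mm per SD, and κ ~ N(0, 1) — chosen once as a
  plausible spectrum for a bone of this size;
* **demographics** sampled to match the cohort the method targets: weight
  75.3 ± 15.9 kg, height 1.71 ± 0.08 m, age 50 ± 18 y, 41% male;
* **soft-tissue offsets** between bone and skin landmarks, linear in
  centered weight, BMI, sex and age with the largest magnitudes at AI
  (e.g. 0.08 mm/kg on AI.z) and sex effects at AA, plus isotropic noise of
  SD 0.3 mm.

The offsets are specified in each subject's own body-fixed frame, which is
itself built from the skin landmarks; the generator resolves this
circularity with a short fixed-point iteration (skin = bone + Rᵀ·offset),
so that in the induced frame skin − bone equals the generating linear model
*exactly*. That makes regression parameter recovery a sharp test: with the
default noise, the fold-scored selection recovers the generating predictors
with coefficients within 15% for at least 9 of the 12 responses.

What the generator does **not** emulate: real scapular anatomy (glenoid,
acromion, coracoid geometry), segmentation artifacts, landmark palpation
error structure beyond isotropic noise, posture-dependent soft-tissue
shifts, and the long eigenvalue tail of real shape populations (it has
exactly five modes). Passing tests therefore demonstrate the correctness
and statistical behaviour of the algorithms, not clinical accuracy on real
shoulders.

## Numerical choices and problem sizes

* Remeshing (`remesh_isotropic`) follows the explicit split/collapse/flip/
  tangential-relax scheme with target edge length derived from surface area
  and the requested count, a link-condition and fold-over guard on every
  collapse, and a final exact-count pass so all corresponded shape vectors
  are fixed-size. Watertightness is preserved down to extreme decimation
  (Euler characteristic 2 at 10 vertices in the tests).
* Nearest-point queries use exact point-to-triangle projection over
  candidate faces from the k = 8 nearest vertices.
* The ICP cost floor is ~1e-7 mm (floating-point cancellation in the
  blocked distance computation), which bounds the meaningful tolerance of
  "identity" assertions.
* Tests run the pipeline at reduced sizes chosen for statistical
  sharpness per minute of compute: 642-vertex templates for cohort-level
  tests, 162 for plumbing tests, a 56-subject 6000-vertex cohort in the
  acceptance script, and GA settings of population 30 / 50 generations for
  batch reconstructions (the default 50/100 is used for single
  reconstructions).
* Fitted models are serialized with R's native RDS (`save_model` /
  `load_model`), which round-trips arrays bit-identically.

## Known limitations

* The non-rigid correspondence is a standard TPS-plus-projection scheme;
  groupwise or minimum-description-length correspondence would likely give
  cleaner modes on real data.
* Each bone coordinate is regressed independently; cross-axis anatomical
  correlations are ignored by construction.
* The exponential penalty's shrinkage bias (above) means landmark fits are
  conservative for weakly landmark-coupled modes; if unbiased weight
  recovery matters more than population plausibility, expose
  `penalty_weight` and reduce it.
* Reconstruction uses the four landmarks only — no surface or image term —
  so accuracy away from the landmarks rests entirely on the shape prior.
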