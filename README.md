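# scapssm

Reconstruction of subject-specific right-scapula surfaces from four
digitized **skin** landmarks and demographics, using a PCA statistical
shape model (SSM), stepwise skin-to-bone landmark regression, and penalized
landmark-fitting optimization.

## Who this is for

Motion-capture and musculoskeletal-modeling workflows can palpate the
scapular landmarks AA (acromial angle), TS (root of the spine), AI
(inferior angle) and AC (acromioclavicular joint) at the skin, but the
underlying bone geometry normally requires CT/MRI segmentation. `scapssm`
estimates the full bone surface from the skin landmarks plus sex, age,
weight and height alone.

## The method

1. **Shape model.** Corresponded scapula meshes (rigid ICP + thin-plate
   spline / projection non-rigid registration onto a template) are
   decomposed by PCA: shape(κ) = x̄ + Σₘ κₘ σₘ φₘ, with weights κ in
   standard-deviation units and no scale normalization, so overall size is
   itself a mode. Validated by compactness, generalization and
   specificity.
2. **Skin-to-bone regression.** In the ISB body-fixed scapular frame
   (origin AA, z along TS→AA, x anterior plane normal), each of the 12
   bone-landmark coordinates is regressed on 17 predictors (6 free skin
   coordinates, 6 inter-landmark distances, sex, age, weight, height,
   BMI) by stepwise selection with partial-F entry/removal p-values
   0.05/0.10, fitted on 10 shuffle splits (70/30) and selected by the
   fold score s = ½[(MAE_train+MAE_test)/2 + |MAE_train−MAE_test|].
3. **Reconstruction.** The predicted bone landmarks become the target of
   f(κ) = ‖x_target − x(κ)‖² + Σₘ(exp(κₘ²) − 1), minimized over the first
   M = 5 mode weights by a seeded genetic algorithm followed by bounded
   quasi-Newton refinement; x(κ) is rigidly aligned to the target inside
   the objective.

Quality is reported as landmark-to-landmark (L2L) and surface-to-surface
(S2S) errors, with Kruskal–Wallis tests comparing digitized- vs
predicted-landmark reconstructions.

Because real cohorts of this kind are access-controlled, the package
includes a first-class synthetic population generator
(`population_config()` / `generate_cohort()`) with exact ground truth —
known modes, known soft-tissue offset coefficients, demographics matching
the target cohort statistics — against which every stage is validated.

## Worked example

```r
library(scapssm)

# 1. simulate a small corresponded cohort with known ground truth
cfg <- population_config(n_subjects = 30, template_vertices = 642, seed = 7)
cohort <- generate_cohort(cfg)

# 2. statistical shape model from the corresponded shapes
ssm <- build_ssm(cohort$shapes, faces = cohort$template$mesh$faces,
                 landmark_indices = cohort$template$landmark_indices)
print(ssm)
#> scapula_ssm: 30 training shapes, 642 vertices, 5 modes
#>   mode SD (mm): 115.18, 49.8, 34.8, 19.61, 12.58
#>   95% of variance in 3 mode(s)
#>   landmark vertices: AA=6 TS=8 AI=25 AC=268

# 3. skin-to-bone regression (body-fixed frames built internally)
reg <- cohort_regression_data(cohort$skin, cohort$bone, cohort$subjects)
fit <- fit_skin_to_bone(reg$X, reg$Y, seed = 7)
print(fit$models$AI.z)
#> stepwise_fit: 2 predictor(s), R2 0.998 (adj 0.998)
#> (Intercept)        AI.z      weight
#>      2.8335      0.9962     -0.0800

# 4. reconstruct one subject from its skin landmarks + demographics
frame <- build_isb_scapula_frame(cohort$skin$S003)
predictors <- assemble_predictors(to_body_frame(cohort$skin$S003, frame),
                                  cohort$subjects$S003)
target <- predict_bone_landmarks(fit, predictors)
problem <- reconstruction_problem(ssm, target, M = 5)
rec <- reconstruct(problem, seed = 7)
print(rec)
#> scapula_reconstruction: M = 5, f = 1.977 (data 0.4056 + penalty 1.571)
#>   kappa*: 0.941, 0.138, 0.074, 0.005, -0.338
#>   landmark residuals (mm): AA=0.224 TS=0.425 AI=0.282 AC=0.309

# 5. quality against the ground-truth surface
s2s <- s2s_error(rec$mesh, cohort$shapes$S003)
cat(sprintf("S2S RMSE vs ground truth: %.2f mm\n", s2s$rmse))
#> S2S RMSE vs ground truth: 0.69 mm
```

Reading the output: the generator planted a weight dependence of
−0.08 mm/kg on the AI.z bone coordinate, and the selected regression
recovers it (coefficient −0.0800, with ~1 on the subject's own AI.z skin
coordinate). Sub-half-millimetre landmark residuals and a 0.69 mm
surface RMSE mean the five-mode fit essentially recovered this subject's
shape; the penalty term in f keeps the weights inside the plausible range.

The same pipeline is scriptable from a shell via `inst/cli/scapssm`
(`simulate`, `build-ssm`, `fit-regression`, `reconstruct`, `evaluate`,
each taking `--config file.yaml --seed N`).

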