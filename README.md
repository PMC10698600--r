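# lungmorph

Quantitative analysis of neonatal chest MRI for bronchopulmonary dysplasia
(BPD) research: synthetic phantoms with analytic ground truth, multi-rater
2D U-Net ensemble lung segmentation fused by pixelwise majority voting, 3D
lung reconstruction from anisotropic axial stacks, a fixed roster of 78
morphologic lung features, and nested cross-validated severity models.

It is written for imaging scientists and neonatology researchers who need
the full measurement chain — image → mask → 3D lung → feature vector →
severity model — as testable, seedable R functions, plus a phantom bench
that provides closed-form truth for every stage.

## The core quantities

* **Volumetric Dice coefficient (VDC)** between masks A and B, always over
  the whole 3D stack: `VDC = 2|A∩B| / (|A| + |B|)`.
* **Majority-vote ensemble**: a voxel is lung iff strictly more than half
  of the per-rater model predictions say so.
* **78 lung features** (39 per lung; 38 volumetric / 30 intensity / 10
  surface overall), computed in world mm on the native anisotropic grid
  (axis order AP, LR, CC; craniocaudal spacing = slice pitch = section
  thickness + gap). Highlights: elongation = major/minor
  equivalent-ellipsoid axis length (from the inertia eigenvalues,
  `axis = 2√(5λ)`); intensity AP centroid displacement =
  (intensity-weighted − geometric AP centroid) / AP extent; volumetric
  surface roughness = mesh area / convex-hull area (≥ 1, = 1 for smooth
  convex shapes); solidity = lung voxels / convex-hull voxels (≤ 1).
* **Nested stratified 5×5-fold cross-validation with 10 repetitions** for
  elastic-net logistic regression and random forests over the feature
  groups L (lung MRI), P (patient attributes), C (clinical adaptation),
  reported as pooled-prediction AUC (macro-weighted one-vs-rest for the
  4-grade multinomial scenario); penalized Poisson / random-forest
  regression with MAE for ventilation- and oxygen-day counts.

## Worked example

```r
library(lungmorph)

# a seeded phantom: torso + two ellipsoidal lungs, analytic truth attached
ph <- generate_phantom(phantom_spec(
  grid_shape = c(64, 64, 14), spacing = c(2, 2.5, 5),
  left_semi_axes = c(22, 16, 18), right_semi_axes = c(24, 18, 19),
  left_center = c(64, 48, 35), right_center = c(64, 110, 35),
  noise_sd = 0.05, seed = 1))
ph$truth$left$volume_mm3
#> [1] 26540.17

# three simulated raters, one U-Net per rater, majority-vote ensemble
raters <- simulate_raters(ph$mask, n_raters = 3, boundary_jitter_mm = 1.5, seed = 2)
models <- lapply(1:3, function(r)
  train_segmenter(list(ph$volume), raters[r],
                  seg_config(depth = 3, base_channels = 8, epochs = 40,
                             learning_rate = 3e-3, seed = r)))
ensemble <- majority_vote(lapply(models, predict_mask, volume = ph$volume))
volumetric_dice(ensemble, ph$mask)
#> [1] 0.9107901

# 3D reconstruction and the 78-feature vector
rec <- reconstruct_lungs(ensemble, ph$volume)
fs  <- extract_features(rec)
fs
#> <lung_feature_set 'phantom_seed1'> 78 features (intensity 30, surface 10, volumetric 38 )
dplyr::filter(tidy(fs), base == "elongation")
#> # A tibble: 2 × 7
#>   name             side  base       category   units description               value
#>   <chr>            <chr> <chr>      <chr>      <chr> <chr>                     <dbl>
#> 1 left_elongation  left  elongation volumetric ""    major / minor equivalen…   1.41
#> 2 right_elongation right elongation volumetric ""    major / minor equivalen…   1.51

# severity modelling on a synthetic cohort with planted effects
co  <- generate_cohort(cohort_spec(n_subjects = 200, seed = 3))
res <- nested_cv_classify(build_design(co, "PCL"), scenario = "bpd_any",
                          plan = cv_plan(repetitions = 10, seed = 4),
                          search_budget = 8)
glance(res)[, c("scenario", "selector", "mean_auc", "sd_auc")]
#> # A tibble: 1 × 4
#>   scenario selector mean_auc sd_auc
#>   <chr>    <chr>       <dbl>  <dbl>
#> 1 bpd_any  PCL         0.893 0.0167
```

The analytic truth (26,540 mm³) is the closed-form ellipsoid volume of
the left phantom lung. The ensemble VDC of 0.91 says the fused prediction
recovers the ground-truth lung to ~91% voxel overlap after training three
single-subject models; the elongation values (1.41 / 1.51) are the
major/minor equivalent-axis ratios of the two phantom lungs; the mean AUC
of 0.89 ± 0.02 across repetitions reflects the planted feature–severity
effects in the synthetic cohort (a null cohort gives ~0.5).

A thin command-line interface over the same functions lives in
`inst/cli/lungmorph.R` (subcommands `phantom`, `cohort`, `segment`,
`reconstruct`, `features`, `classify`, `regress`, `run`), and
`run_pipeline()` orchestrates the full chain with a content-hashed run
manifest.

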