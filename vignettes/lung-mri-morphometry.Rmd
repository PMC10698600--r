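---
title: "Quantitative neonatal lung MRI: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative neonatal lung MRI: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bronchopulmonary dysplasia (BPD) is the chronic lung disease of preterm
birth, graded none / mild / moderate / severe by the oxygen-supplementation
need. Chest MRI near term age shows both how large and how structurally
altered the lungs are, but turning free-breathing neonatal T2-weighted
stacks into numbers requires a chain of steps: segmenting the lungs on
every axial slice, fusing several imperfect annotations, rebuilding a
physically scaled 3D lung from thick anisotropic sections, summarizing the
result as a fixed roster of morphologic features, and relating those
features to disease severity without fooling oneself with leakage.
`lungmorph` implements that chain end to end, together with a synthetic
phantom generator that provides analytic ground truth so every stage can be
tested quantitatively on a desk.

All volumes use the axis order (AP, LR, CC) — anteroposterior, left-right,
craniocaudal — with physical spacing in mm. The default acquisition
geometry is 1.3 × 1.9 mm in plane with a 4.4 mm slice pitch (4 mm sections
plus a 0.4 mm gap); the pitch, not the section thickness, is the effective
CC voxel size, and all volumes and features are computed in world mm so the
gap is never silently dropped. Voxel indices are 0-based with world
coordinate `index * spacing`.

## The phantom generator: what it emulates and what it does not

`phantom_spec()` / `generate_phantom()` build a torso-like elliptical
cylinder of bright tissue containing two dark, roughly ellipsoidal lungs.
The generator's knobs map one-to-one onto the effects the pipeline must
withstand: additive Gaussian signal noise (`noise_sd`, default 0.04 on a
0.05–0.55 a.u. intensity scale), an optional anteroposterior intensity
gradient inside the lungs (`ap_gradient_slope`, intensity per mm — the
gravitational ventilation-inhomogeneity surrogate), an optional smooth
radial boundary perturbation (`surface_perturbation_amplitude`, the RMS
displacement in mm, implemented as a seeded band-limited modulation of the
ellipsoid radius), and an optional partial-volume blur. Every phantom
carries its analytic truth: ellipsoid volumes $\tfrac43\pi abc$, centroids,
semi-axes, and — for smooth ellipsoids — the Knud Thomsen area
approximation $4\pi\left(\frac{(ab)^p+(ac)^p+(bc)^p}{3}\right)^{1/p}$ with
$p = 1.6075$ (≤ 1.06 % relative error), against which the voxel pipeline is
checked.

Rater variability is emulated geometrically rather than by intensity
tricks: `simulate_raters()` perturbs the exact signed Euclidean distance to
the mask boundary by a smooth unit-variance noise field scaled by
`boundary_jitter_mm`, so the jitter parameter *is* the SD of the boundary
displacement in mm. Zero jitter returns bit-identical copies; growing
jitter lowers interrater Dice monotonically.

The cohort generator (`cohort_spec()` / `generate_cohort()`) draws severity
grades from stated proportions (default 0.38 / 0.28 / 0.12 / 0.22), patient
attributes (gestational age falling ~1.1 wk per grade step around 30.5 wk,
correlated birth weight and body size, sex), clinical adaptation (5-minute
Apgar, early-onset infection and steroid flags with grade-dependent rates),
ventilation and oxygen days as negative-binomial counts with
grade-dependent means (overdispersed on purpose, so the Poisson regressor
is exercised under misspecification), and a 78-feature vector with
*planted* standardized shifts per grade step. With all effect sizes zero
the features are exactly independent of the grade — the null condition the
classifier suite must not beat.

What the phantoms deliberately do not model: MR physics (relaxation, coil
profiles, bias fields), motion or ghosting artifacts, lobar anatomy, and
the correlation structure of real lung features (cohort features are
independent Gaussians up to the planted shifts). Passing the suites
therefore demonstrates that the *machinery* is correct and leak-free — not
that real neonatal cohort performance is reproduced, which requires the
clinical data.

## Segmentation: per-rater U-Nets and majority voting

One compact 2D U-Net is trained per rater (`train_segmenter()`), and the
per-model predictions are fused pixelwise by strict majority
(`majority_vote()`): a voxel is lung iff more than half the members say so.
With an even member count, exactly tied voxels go to background and the tie
count is surfaced in an attribute — conservative and visible rather than
hidden; the reference configuration votes over three members where ties
cannot occur.

The network is implemented in the package (RcppArmadillo kernels for
im2col convolution, 2×2 max pooling and nearest upsampling; the training
loop, Adam and the loss in R). It is a standard encoder–decoder with skip
connections: `depth` resolution levels, `base_channels` doubling per level,
3×3 convolutions with ReLU, a 1×1 sigmoid head. The default loss is soft
Dice plus binary cross-entropy — the usual remedy for the strong
foreground/background imbalance of lung slices; the binarization threshold
defaults to 0.5. Analytic gradients are verified against central finite
differences in the test suite (relative error < 1e-4 on sampled weights),
which is the strongest available correctness guarantee for a from-scratch
network. Model input is normalized per volume to [0, 1] by robust
1st/99th-percentile scaling; the raw intensities are kept untouched for the
feature stage. Training is fully seeded (weight init, shuffling, flips),
so identical configs reproduce identical weights.

Concordance is measured with the volumetric Dice coefficient,
$\mathrm{VDC}(A,B) = 2|A\cap B|/(|A|+|B|)$, always over the whole 3D stack,
never slice-averaged; both masks empty is a defined error rather than a
silent 1. On phantom benches the small default network (depth 3, 8 base
channels, 20 epochs, 8 training subjects at 64×64 in-plane) reaches
held-out Dice well above the 0.85 floor in about a minute of CPU time; the
test suite and the acceptance script use exactly these sizes to stay within
desk-scale budgets.

## Reconstruction and the canonical frame

`reconstruct_lungs()` labels the thresholded mask under 26-connectivity
(the most permissive standard connectivity, chosen so thin apices spanning
4.4 mm sections are not split), keeps the two largest components, discards
smaller specks with a warning, and assigns left/right by the LR centroid
(left = smaller LR world coordinate). Rather than resampling to isotropic
voxels, all geometry is computed in world mm on the native grid —
resampling would alter the raw intensities the intensity features need.

`align_reference_frame()` rotates to a canonical frame defined by the
principal inertia axes of the *combined* two-lung mask (a per-lung frame
would destroy cross-lung comparability of centroid features). Two design
points deserve spelling out, because the obvious alternatives are subtly
wrong:

* *Axes are assigned by anatomy, not by eigenvalue order.* Each principal
  axis is matched to the anatomical axis (AP, LR, CC) it is most aligned
  with in the acquisition frame. A magnitude rule ("longest axis is CC")
  silently relabels the axes whenever the left–right separation of the
  two lungs dominates the inertia — which it does for side-by-side lungs —
  and with it every axis-named feature. The acquisition axes of an axial
  chest stack are anatomically meaningful, so they anchor the matching;
  the rotation still comes entirely from the inertia eigenvectors.
* *Axis directions are geometric and deterministic.* The LR axis points
  from the left towards the right lung centroid; the CC sign makes the
  shape skewness of the voxel coordinates along CC non-negative (falling
  back to the acquisition CC direction when the skewness is numerically
  zero, |skew| < 1e-3); AP completes the right-handed frame as LR × CC,
  so the rotation is proper (det +1) by construction. An
  intensity-weighted sign rule was rejected because it ties the AP
  direction to the intensity distribution itself — for a symmetric lung
  with a linear AP gradient of slope $b$ the weighted third moment is
  $-2b/15 + O(b^3)$, so the frame would flip exactly when the gradient
  (the quantity the AP displacement feature measures) grows.

Near-spherical shapes with degenerate inertia fall back to the current
frame with a warning. Alignment is metadata (a stored rotation and centre
applied to coordinates on the fly), so volumes are exactly invariant under
it and aligning twice is idempotent.

## The 78 features

`extract_features()` emits exactly 78 named values — 39 per lung, split 19
volumetric / 15 intensity / 5 surface, i.e. 38/30/10 overall — with frozen
names, category tags and units kept in one manifest
(`feature_manifest()`); the roster hash is a regression test. Highlights
and conventions:

* **Volumetric** — volume (voxels × voxel volume); bounding-box extents
  (range + one voxel); centroids in the canonical frame; principal second
  moments (eigenvalues of the second-central-moment tensor with the voxel
  self-moment `spacing²/12` added — without it, coarse 4.4 mm sections
  bias the CC moment low); equivalent-ellipsoid axis lengths
  $2\sqrt{5\lambda}$; elongation = major/minor axis length (exactly 2 for
  a 30:15 ellipsoid, and ≥ 1 by construction); equivalent-sphere diameter;
  extent; axis-aligned second moments.
* **Intensity** — descriptive statistics of the raw (never re-normalized)
  lung voxel intensities, including a 32-bin histogram entropy in bits;
  intensity-weighted centroids; and the normalized displacements
  (weighted − geometric centroid)/extent along AP and CC. The raw
  intensities are the centroid weights, shifted only when negative values
  are present: subtracting the minimum unconditionally would make the
  weights proportional to the intensity *contrast* and erase the
  magnitude of the very gradient the displacement feature measures. The
  normalization by the lung's own extent makes the displacement
  dimensionless and body-size free. A constant-intensity lung returns
  skewness/kurtosis 0 with an explicit flag.
* **Surface** — the binary label is smoothed with a spacing-aware Gaussian
  (σ = 1 voxel per axis) and iso-surfaced at 0.5 by marching tetrahedra
  (each cell split into six tetrahedra, vertices by linear interpolation;
  chosen over table-based marching cubes so the implementation is fully
  self-derived, with identical asymptotics). The smoothing is essential:
  iso-surfacing a raw binary mask yields a staircase whose area
  overestimates a sphere by ~9 %, while the smoothed surface is accurate
  to ~1 %. Mesh area, surface-to-volume ratio, convex-hull area (3D
  quickhull over the mesh vertices), volumetric surface roughness =
  mesh area / hull area (floored at its convex limit 1; sub-1 values are
  triangulation noise), and solidity = lung voxels / rasterized-hull
  voxels (capped at 1) follow. The rasterized-hull convention for solidity
  matches common region-properties practice and avoids the half-voxel
  "skin" bias a continuous hull volume would introduce on coarse grids.

Invariants covered by tests: whole-voxel translations leave
canonical-frame features unchanged; isotropic ×2 scaling multiplies
volumes by 8, areas by 4, lengths by 2 and leaves ratios fixed (3 %
tolerance); mirroring swaps the left/right blocks; growing surface
perturbation strictly raises roughness and lowers solidity; a growing AP
gradient strictly raises the AP centroid displacement.

## Severity models without leakage

`build_design()` assembles design matrices from the feature groups — L
(the 78 lung features), P (gestational age, birth weight, body size, sex),
C (Apgar, early-onset infection, steroids) — or the GA-only baseline,
excluding subjects with missing values with a logged count.
`nested_cv_classify()` runs a repeated, stratified nested cross-validation
(5 outer × 5 inner folds, 10 repetitions by default): hyperparameters are
drawn by randomized search (default budget 50; the tests and the
acceptance script use 6–8 draws to stay within desk budgets) and scored on
pooled inner-fold predictions; scaling, univariate ANOVA-F selection (k
tuned by the inner loop) or PCA (component count tuned) are fitted strictly
inside training folds. Outer-fold predictions are pooled per repetition
before computing the AUC — with as few as a dozen subjects in a class,
per-fold AUCs are too unstable — and the summary is the mean ± SD *across
repetitions* (the package states this choice explicitly because the
alternative, SD across folds, measures something else). Multinomial AUC is
one-vs-rest, prevalence-weighted, with the unweighted mean reported
alongside; for balanced classes the two coincide (tested). Models are
elastic-net logistic regression (glmnet; binomial or multinomial) and
probability random forests (ranger); one-column designs fall back to an
unpenalized GLM.

Two safety properties are tested rather than assumed: a null cohort yields
a mean AUC within [0.45, 0.55], and a canary column that encodes the label
in outer *test* folds only (noise in training folds) does not lift the
AUC — the canary would be selected by any feature-selection or scaling step
that illegally saw test data.

`nested_cv_regress()` estimates ventilation/oxygen days with an
elastic-net-penalized Poisson regression (with p of the order of n an
unpenalized Poisson GLM separates and its exponential link overflows on
held-out data; predictions are additionally capped at 10× the training
maximum so the MAE is always finite) or a random forest, reporting MAE per
repetition. `permutation_importance()` gives seeded mean-AUC-drop
importances (100 repeats by default), and `feature_correlation_matrix()` /
`severity_group_tests()` provide the exploratory battery: Spearman
correlations with Bonferroni-adjusted flags, Kruskal-Wallis across grades
and Bonferroni-corrected pairwise Mann-Whitney tests.

## Numerical choices and degenerate inputs

* Crop windows (`crop_to_model_grid()`) are centred on the 3D intensity
  centre of mass — deterministic and robust to off-centre torsos — with
  one window per subject so masks crop congruently; too-small inputs are
  symmetrically zero-padded.
* Binary masks are validated strictly ({0,1} only), NaN/Inf anywhere is a
  refusal, spacing must be positive, and a NIfTI without usable spacing is
  an error telling the user how to supply it.
* Ties in max pooling route the gradient to the first maximum; even-count
  vote ties go to background with a surfaced count; eigen-decomposition
  sign ambiguity is resolved as described above; both-empty Dice, empty
  lungs, single-component masks and sub-8-voxel meshes are errors that
  name the offending object.
* Problem sizes in the tests and the acceptance script (64×64 in-plane
  training grids, 200-subject cohorts, 10 CV repetitions, reduced search
  budgets) were chosen as the smallest sizes at which the tested
  properties are stable; they are the package's stated desk-scale bench.

## Known limitations

The cohort generator plants independent Gaussian features; real lung
features are strongly correlated, so feature-selection behaviour on real
data may differ. The canonical frame is an inertia-axis construction and is
not claimed to equal any particular clinical alignment procedure. The
2D-slice-wise network is the only architecture on purpose (a 3D variant is
out of scope), and clinical headline numbers (cohort Dice or AUC values)
are not reproducible from synthetic data — the package's claims end at the
analytic and property-based benches described here.
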