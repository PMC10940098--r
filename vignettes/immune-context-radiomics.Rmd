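---
title: "Methods: CT radiomics biomarkers of the lymphoid and myeloid immune context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT radiomics biomarkers of the lymphoid and myeloid immune context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic generator does and does not emulate, and
the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The problem and the model

The tumor immune microenvironment carries prognostic and predictive
information. Its two major compartments pull in opposite directions:
lymphoid infiltration (CD3+/CD8+ T cells) is favorable, myeloid
infiltration (CD66b+ granulocytes) unfavorable. The reference standard is
immunohistochemistry: cell counts in the intratumoral and peritumoral
regions are dichotomized at training-cohort medians (a count scores 1 iff
it is **greater than or equal to** its median) and summed into a lymphoid
immune score (LIS, 0–4; "high" = 2–4) and a myeloid immune score (MIS,
0–2; "high" = 1–2). The package's purpose is a noninvasive surrogate: two
logistic radiomics signatures over intratumoral and peritumoral CT
features — the lymphoid radiomics score (LRS) and myeloid radiomics score
(MRS) — each dichotomized at a Youden cutoff, whose status pair defines
four immune subtypes: 1 (−/−), 2 (+/−), 3 (−/+), 4 (+/+), with LRS first.

## 2. Region geometry

All morphology is computed in millimetres via an exact 3D Euclidean
distance transform (Felzenszwalb–Huttenlocher, anisotropic spacing), not
iterated structuring elements: the band widths are physical quantities and
must not depend on voxel pitch. Volumes are resampled to 1 mm isotropic
voxels first (trilinear for intensities, nearest-neighbor for masks).

Distances are measured voxel-center to voxel-center. The peritumoral band
is the union of (a) background voxels within 2 mm of a tumor voxel and
(b) tumor voxels within 1 mm of a background voxel — a 3 mm ring spanning
the invasive margin. Under these semantics a single-voxel tumor at 1 mm
spacing produces the 33-voxel discrete Euclidean ball of radius 2. Two
consequences worth knowing:

* **Intratumoral region.** The ring's inner 1 mm band belongs to the ring,
  so the default "center" region is the tumor minus that band
  (`intratumoral = "eroded"`), keeping the two regions disjoint — which the
  pair validator checks. `intratumoral = "full"` is available for users who
  want the whole tumor as the center; the validator then reports the
  overlap rather than silently accepting it.
* **Digitization bias.** Center-to-center dilation under-reaches diagonal
  directions by up to half a voxel, so the digital ring of a large sphere
  sits slightly *inside* the analytic shell `(4/3)π[(r+2)³ − (r−1)³]`; the
  deficit is a surface-layer effect (bounded by a ~0.55-voxel skin on the
  shell surfaces, roughly 10% of a 3 mm shell at 1 mm pitch) and does not
  vanish with radius. The geometry tests assert exactly this bound rather
  than pretending the digital and continuous volumes coincide.

Exclusion masks (air cavities, vessels, adjacent organs) are caller
inputs; the package removes them from the ring and flags an empty ring
rather than guessing how they were produced.

## 3. The 584-feature inventory

Per region: 8 shape + 14 first-order + 90 texture statistics × 3
quantizations = 292; intratumoral + peritumoral = 584. The texture block
is GLCM 39 (13 Haralick-type statistics × {direction mean, direction
range, merged matrix} over the 13 unique 3D unit offsets, symmetric,
distance 1), GLRLM 16 (run matrices summed over the 13 directions), GLSZM
16 (26-connected zones), GLDM 14 (26-neighborhood, dependence threshold
α = 0, dependence size counts the center, 1–27), NGTDM 5. The inventory is
configuration-driven; the reference configuration reproduces the
8/14/270/292/584 counts exactly, which the acceptance suite asserts.

Choices that matter:

* **Discretization** is fixed bin *count* (16/32/64 equal-width bins over
  the in-mask range), so texture features are invariant to affine
  intensity rescaling — the right robustness for phantoms whose intensity
  scale is arbitrary. First-order entropy/uniformity use a fixed 32-bin
  histogram.
* **Surface area** uses the coarea formula — the integrated gradient
  magnitude of a Gaussian-smoothed (σ = 1 voxel) indicator — because no
  marching-cubes mesher is available as a dependency and raw voxel-face
  counting overestimates sphere areas by ~50%. The estimator tracks
  analytic spheres within a few percent (tested), which keeps sphericity
  of a 10 mm digital sphere inside [0.95, 1.05].
* **Zero-variance conventions**: skewness/kurtosis of constant regions are
  0, GLCM correlation of a degenerate matrix is 1, single-voxel regions
  return all-zero texture with a `degenerate` flag — NaNs must never reach
  the selection cascade.
* **Axis lengths** come from PCA of voxel-center coordinates
  (`4·sqrt(eigenvalue)` extents); elongation and flatness are
  `sqrt(λ2/λ1)` and `sqrt(λ3/λ1)`, so a 2:1 prolate ellipsoid has
  elongation ≈ 0.5.

Every texture statistic is verified to 1e-10 against a brute-force
enumeration oracle (naive matrix construction *and* naive statistic
formulas) on random grids up to 8³ with up to 4 gray levels, plus
rotation-consistency and shift/scale-invariance property tests.

Feature reproducibility uses ICC(2,1) — two-way random effects, absolute
agreement, single rater — from ANOVA mean squares, with the conventional
0.75 retention threshold. The analysis workflow emulates a second observer
by a one-voxel erosion/dilation jitter of the mask.

## 4. Signature construction

The cascade, run once per target (lymphoid, myeloid), pools intratumoral
and peritumoral features (the printed per-region splits of the selected
features are outcomes of selection, not constraints, so a pooled cascade
is the cleaner design):

1. optional ICC filter (≥ 0.75);
2. z-score normalization (population SD), training parameters frozen and
   reapplied to any validation data; constant features dropped loudly;
3. greedy mRMR, quotient criterion MI(f; y) / mean MI(f; selected), with
   plug-in MI on 3-bin equal-frequency discretization (features with ≤ 3
   distinct values keep their own levels — quantile binning would collapse
   binary features to a single bin). k = 30 retained: large enough that
   the downstream selectors see real competition, small enough that
   SVM-RFE stays fast; the source text does not state a k.
4. collinearity pruning in rank order at |r| > 0.9 (the "collinearity
   reduction algorithm" is unnamed in the source; rank-ordered pairwise
   pruning is the stated design choice);
5. LASSO logistic regression (glmnet, 100-point penalty path) and linear
   SVM-RFE (cost 1, drop the 10% smallest squared weights per step,
   elimination order fixed on the full training data), both choosing their
   operating point by maximum mean cross-validated AUC over seeded
   stratified 5-fold splits; the **overlap** of the two selected sets goes
   forward. If the overlap has fewer than 2 features the LASSO set is used
   (flagged); if that is empty too, the top-2 decorrelated mRMR features
   (flagged). The fallback keeps the pipeline total on degenerate inputs.
6. unpenalized multivariate logistic regression; the score is the linear
   predictor including the intercept (a pure location shift that the
   cutoff absorbs). Perfect separation (non-convergence or |coef| > 15 on
   normalized features) triggers a ridge-stabilized refit (λ = 1e-6),
   flagged.
7. Youden cutoff on training scores: the observed threshold maximizing
   sensitivity + specificity − 1 under "high iff score ≥ cutoff", smallest
   maximizer on ties. Median and quartile cutoffs are reported alongside
   as sensitivity analyses.

Models serialize to JSON (features, coefficients, normalization, cutoff)
and round-trip exactly.

## 5. Outcome statistics

Standard machinery is delegated to the survival package behind the module
surface: Kaplan–Meier with Greenwood bands, log-rank, Cox partial
likelihood with **Breslow** tie handling (Efron is one argument away; the
source does not state its choice), and the Schoenfeld-residual PH test on
the Kaplan–Meier transform of time with the printed decision rule (global
p < 0.05 ⇒ "violated"). Harrell's C is a direct all-pairs enumeration
(ties in the predictor count 0.5), cross-checked by an independent audit.
The nomogram is implemented as its scoring mathematics only — per-covariate
points `100·β(x − x_min)/max_j β_j·range_j` and the total-points affine
transform of the linear predictor (identical C-index by construction);
graphical rendering is cosmetic and out of scope. ORR tables switch from
Pearson χ² to Fisher's exact test when any expected cell is below 5.
ROC AUC is the tie-corrected rank statistic with DeLong
structural-component variance, and the paired DeLong z-test compares
correlated models (CPS alone vs the fitted LRS+MRS and CPS+LRS+MRS
logistic combinations). pROC serves as an independent cross-check in the
tests, never as the implementation.

Shapley attribution is exact interventional enumeration over all feature
coalitions against the background sample mean, feasible for ≤ 15 features
(the intended use — 2 imaging scores plus ~10 covariates — fits well
inside); beyond that a seeded permutation estimator takes over. Efficiency
(attributions sum to `f(x) − f(background)`) holds to 1e-10 and is
asserted, as is the linear-model closed form `β_i(x_i − mean_i)`.

No multiplicity correction is applied across subgroup analyses, matching
the apparent practice of the source analyses; consumers should treat
subgroup p values accordingly.

## 6. The synthetic cohort generator

The generator is a first-class module defining the study conditions, not a
test fixture. Per patient it draws a latent bivariate-normal
(lymphoid, myeloid) context (correlation `rho`), then:

* **Phantom images**: an ellipsoidal tumor (semi-axes uniform 8–14 mm) in
  a padded grid; interior intensity = 60 + a stationary noise field. The
  field is white noise smoothed by a Gaussian whose width grows with the
  myeloid latent (correlation length: 1.0 + 0.25·latent voxels, clamped to
  [0.3, 2.5]) and rescaled so the within-mask SD is exactly
  `10 + 3·lymphoid latent` (floored at 0.5). Rescaling makes the variance
  readout exactly monotone in the latent, which the tests exploit.
* **IHC counts**: negative binomial (dispersion 2; Poisson is the
  large-dispersion special case) with log-mean slopes `count_effect` on
  the matching latent; CD3/CD8 follow the lymphoid latent, CD66b the
  myeloid one.
* **Covariates** (age, sex, location, differentiation, size, Lauren,
  CEA/CA19-9, chemotherapy, stage) are drawn independently of the latents,
  so "independent predictor" claims in multivariate Cox models are
  testable under a known truth.
* **Outcomes**: LIS/MIS are scored against the cohort's own medians;
  event times are Weibull (shape 1.2, a mild aging hazard; baseline scale
  48 months) under proportional hazards
  `log h = log(0.26)·[LIS high] + log(3.40)·[MIS high]`, censored by an
  independent uniform draw on (0, 60] months; the objective response is
  Bernoulli with per-subtype probabilities (0.273, 0.533, 0.102, 0.300),
  responders split CR/PR (15% CR) and non-responders SD/PD (50/50). CPS is
  log-normal with a mild loading on the lymphoid–myeloid contrast.

Calibration was chosen once, against the printed operating regime, and
frozen: the hazard ratios are the geometric mid-ranges of the reported
multivariate bands (0.183–0.362 for LIS, 1.971–6.014 for MIS) — note
0.26 × 3.40 < 1, which is exactly why subtype 4 (+/+) outlives subtype 1
(−/−) in both the source and the simulation; the response probabilities
are the printed subtype ORRs; `count_effect = 0.5` puts the AUC *ceiling*
of a perfect latent readout against LIS status near 0.86, so a realistic
imaging signature lands in the published high-0.7s band; `rho = 0.2` is a
configuration guess — the joint lymphoid/myeloid distribution is not
characterized in the source — and is exposed in the config. Everything is
a pure function of config + seed (per-patient seeds are derived by a
seeded draw), which the bitwise-reproducibility test asserts.

What the generator does **not** emulate: CT physics (beam hardening,
reconstruction kernels), scanner and multi-center harmonization, realistic
tumor morphology (phantoms are ellipsoids), spatially structured immune
infiltration within the tumor, informative censoring, or any coupling
between covariates and immune context (a confounded variant can be built
by the caller). Passing tests therefore demonstrate that the *pipeline*
recovers planted structure under its stated assumptions — not that the
biomarkers work on real CT.

## 7. Problem sizes and determinism in the test suite

The suite runs entirely from programmatic fixtures: texture oracles on
grids ≤ 8³; a 300-patient imaging cohort for end-to-end signature
recovery (held-out collapse to chance is checked on a 160-patient null
cohort); 200-replicate null simulations for log-rank and PH test size;
100 replicates each for Cox CI coverage (n = 1000, ~30% censoring) and
LASSO planted-signal recovery (3 of 30 features, 1-SD effects, n = 300);
and a 2000-patient tabular cohort for the subtype response/survival
ordering. All randomness is seeded in the tests; Monte-Carlo bounds are
sized so the fixed-seed checks sit well inside them.

## 8. Interface

The package's functions, the numbered scripts under `analysis/` and this
vignette are the interface; the workflow scripts are thin narrative
drivers over the package and write their tables under `results/`. No
separate shell CLI is shipped — an R user runs the same functions the
scripts do. NIfTI I/O (via RNifti) covers interchange with external
segmentation tools; models serialize to JSON; tables are CSV.

## 9. Known limitations

* The feature inventory is a reference reconstruction matching the printed
  family counts; the original supplementary feature list is not public, so
  individual feature identities (and the published cutoffs −0.1293/−0.2604)
  are not reproducible targets.
* The ring geometry is exact in mm but voxel-center based; sub-voxel
  partial-volume weighting is deliberately out of scope.
* Exact Shapley is exponential in the feature count; beyond 15 features
  only the sampling estimator is practical.
* Imaging-subtype response contrasts in small cohorts are attenuated
  relative to the true-context contrasts (status misclassification ~25%
  at the default calibration); the workflow reports both groupings.
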