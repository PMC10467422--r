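---
title: "Methods: synthetic ICH cohorts and radiomic HE signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ICH cohorts and radiomic HE signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hemorad)
```

`hemorad` builds and validates signatures of early hematoma expansion (HE)
in intracerebral hemorrhage (ICH) from non-contrast head CT. This vignette
is the package's own account of the science: the generative model behind the
synthetic cohorts, the deterministic image pipeline, the feature catalogue
and its conventions, the screening and modelling stages, the statistical
machinery, and the numerical choices made where the design was genuinely
open.

## 1. The prediction problem

HE is a binary outcome defined on volumes: positive when the 24-h follow-up
hematoma exceeds baseline by more than 33% *or* more than 6 ml
(`label_he()`). Candidate predictors fall into three families — 1,130
radiomic features of the segmented hematoma, 8 reader-assessed visual
markers plus the 0–5 BAT score (`bat_score()`: blend sign 1 pt, hypodensity
2 pts, onset-to-CT < 150 min 2 pts), and 5 clinical variables (sex, NIHSS,
GCS, platelets, glucose). Signatures are L1-penalized logistic models fit on
a discovery cohort and evaluated untouched on an independent validation
cohort; onset-to-CT time joins every candidate set except those containing
the BAT score, which already encodes it.

## 2. Synthetic cohort generator

Real trial data being access-restricted, `cohort_spec()` +
`simulate_cohort()` emulate the study population with a *known* planted
effect, so that every pipeline stage is testable against ground truth.

**Lesion rendering** (`generate_lesion()`). A lesion is a random ellipsoid
(semi-axes from a volume drawn lognormally — default mean 12.6, SD 12.7 cm³,
truncated to 0.5–60 cm³ — with mild random anisotropy) whose directional
radius is modulated by a smooth random-bump field on the sphere scaled by
the *irregularity* dial (Beta(2, 6)). The interior is `mean_hu` (Normal,
60 ± 8 HU) plus *heterogeneity* × a unit-variance Gaussian random field with
2 mm correlation length; heterogeneity (lognormal, median 8 HU) controls the
texture families, and heterogeneity = 0 yields an exactly constant interior.
Background tissue is a smooth field clipped to 0–40 HU. Voxels are
anisotropic: 0.46 mm in-plane, slice thickness drawn from discrete scanner
levels (2.5/5/7.5 mm, weighted to mean ≈ 5.2, SD ≈ 1.7 mm). The grid is
sized adaptively to the lesion plus a margin; a fixed grid can be supplied
and errors informatively when too small. All generators are pure functions
of `(spec, patient_index, seed)`.

**Planted effect and calibration** (`generate_tabular()`). The HE
probability is logistic in the *standardized* latent properties with
relative weights (log-volume 0.9, mean density −0.7, heterogeneity 0.5,
irregularity 0.2) whose overall scale κ and intercept are found by
Monte-Carlo inversion (100k latent draws, common random numbers) so that the
population AUC of the true log-odds score equals `auc_target` (default
0.65) at the target prevalence (0.27). The follow-up volume is then drawn
*consistently with the label*: growth exceeds the binding threshold
(min(0.33·baseline, 6 ml)) exactly when the drawn label is positive, so
`label_he()` reproduces it for every patient. Weighting the well-measured
latents (volume and mean density are recovered from features with r > 0.93)
is deliberate: it makes "the extracted features carry the planted signal" a
property of the generator rather than an accident of measurement noise —
with a 3 mm texture correlation length and narrower density spread, the
realized lesion mean is a noisy proxy (r ≈ 0.78) and no analysis could
recover the dialled AUC.

**Clinical tables.** Continuous marginals (glucose 140.4 ± 59.8 mg/dL,
platelets 223 ± 62.3 ×10³/mm³, onset-to-CT 98.1 ± 49.6 min) are Gamma
variables matched by mean/SD — positive support and realistic right skew; a
truncated normal would bias onset-to-CT upward by ~3 SE. NIHSS and GCS come
from the published binned frequencies. Visual markers are Bernoulli with
logit loadings on latent irregularity (shape markers) or heterogeneity
(density markers); per-marker intercepts are calibrated by Monte Carlo so
marginal prevalences match the published table despite the logit-normal
inflation, and `marker_signal = 0` turns the markers into pure marginal
noise (the condition under which combined fits should discard them). mRS
(0–6) is a latent Gaussian loaded on HE (0.9), standardized NIHSS (0.5) and
standardized log lesion volume (0.6 — larger hematomas carry worse
functional outcome, which is what makes volume-heavy signature scores
prognostic), cut at the marginal quantiles, with ~2.9% missingness to
exercise the exclusion path. Repeat segmentations (`generate_repeat_masks()`) perturb the
signed Euclidean distance transform of the mask by a smooth field of scale
`jitter_mm`/2 — local dilations/erosions whose expected Dice against the
original decreases in `jitter_mm` (≈ 0.999 at 1 mm on a 10 mm sphere).

**What the generator does not emulate:** skull/ventricles and anatomy,
scanner reconstruction kernels, intraventricular extension, reader
disagreement structure, and any real coupling between clinical variables and
imaging. Passing tests show the pipeline recovers *planted* structure
through genuine image rendering and measurement; they do not certify
performance on trial data.

## 3. Image pipeline

`preprocess_patient()` chains deterministic steps:

1. **Resampling** to isotropic 1 mm via cubic B-spline interpolation
   (tridiagonal prefilter with whole-point mirror boundary, exact at the
   input samples, constants reproduced exactly; physical extent preserved to
   within one voxel). The binary mask is interpolated linearly and
   re-thresholded at 0.5, which conserves lesion volume across
   anisotropic-to-isotropic changes better than nearest-neighbour
   (configurable).
2. **Cropping** to the mask bounding box + `crop_margin` voxels (default
   12), which bounds the filters' support for speed; the margin is a
   documented approximation for the largest LoG scale and is applied
   identically to every patient.
3. **Derivative images**: one original + 8 undecimated coiflet-1 wavelet
   sub-bands (orthonormal 6-tap filters, letters = L/H per x, y, z axis,
   symmetric half-sample boundary; sub-bands keep the grid so one mask
   indexes all images) + scale-normalized Laplacian-of-Gaussian responses
   σ²∇²(G_σ∗I) at σ = 2, 4, 6 mm (separable Gaussian truncated at 3σ,
   nearest boundary, discrete Laplacian; constants map to exactly zero, and
   the response at a Gaussian blob of scale 4 mm is maximized at σ = 4).
   A decimated orthogonal mode exists solely as a filter-coefficient sanity
   check (sub-band energies sum to the input energy by Parseval).
4. **Re-segmentation** of the mask to 1–200 HU on the original image; the
   re-segmented mask defines the region for *every* image and for shape
   features. Filtering precedes masking because derivative intensities are
   no longer HU. An empty re-segmented mask flags the patient for exclusion.

## 4. Feature catalogue (1,130 per lesion)

14 shape + (18 first-order + 75 texture) × 12 images; names are
`<imageLabel>_<class>_<FeatureName>` in C-locale lexicographic order, a
stable CSV layout.

* **Discretization**: fixed bin width 25 from the per-region minimum
  (applied to derivative intensities too; configurable, bin-count mode
  available). Texture matrices use gray levels 1..max.
* **Texture conventions**: GLCM distance-1 over the 13 unique 3D
  directions, symmetrized, features averaged over directions (not
  merged-matrix); GLRLM maximal runs per direction, averaged; GLSZM zones
  26-connected; NGTDM/GLDM 26-neighbourhoods; GLDM dependence threshold
  α = 0 with dependence size = dependent neighbours + 1.
* **Degenerate-case table** (all logged/tested): one-level region → GLCM
  Correlation = MCC = 1, information measures 0; flat NGTDM → Coarseness
  capped at 10⁶, Contrast/Busyness/Strength 0; zero-variance intensities →
  Skewness = Kurtosis = 0; any residual non-finite value → 0.
* **Kurtosis** is non-excess (normal ≈ 3), stated here because conventions
  differ.
* **Shape**: voxel-based quantities (VoxelVolume, PCA axis lengths 4√λ,
  Elongation √(λ₂/λ₁), Flatness √(λ₃/λ₁), maximum pairwise boundary-voxel
  diameters overall and per axial/coronal/sagittal plane) are exact;
  mesh-based quantities (MeshVolume, SurfaceArea, Sphericity,
  SurfaceVolumeRatio) come from a marching-tetrahedra triangulation of the
  0.5 iso-level of the binary mask after light Gaussian anti-aliasing
  (σ = 0.8 voxel). Meshing the *raw* binary field inflates the surface of a
  digitized r = 20 mm ball by ~8% (sphericity ≈ 0.92); with anti-aliasing
  the ball scores 0.988 with volume within ~1% of the voxel count. The
  tetrahedral decomposition has a preferred cube diagonal, so mesh features
  are rotation-invariant only to ~0.1%; all other aggregated features are
  invariant to 1e-9 under axis-aligned rotations.

## 5. Screening, harmonization, leakage control

* **Stability**: ICC(2,1) (two-way random effects, absolute agreement,
  single measure, standard ANOVA decomposition) across the original and
  perturbed repeat segmentations; retain ICC ≥ 0.90. Undefined ICC (zero
  variance) drops the feature.
* **Collinearity**: greedy elimination on |Spearman ρ| > 0.80 — repeatedly
  take the worst remaining pair and drop the member with the larger mean
  absolute correlation to all remaining features (ties: drop the
  lexicographically later name) — deterministic and order-independent.
  Thresholds are configuration, chosen as common radiomics practice; the
  published reductions (1,130 → 1,002 → 429) depend on the real data and are
  not reproducible targets.
* **ComBat** (optional, default off — the harmonized iteration validated
  worse in the emulated study): parametric empirical-Bayes location/scale
  adjustment per feature with slice-thickness batches, no covariates.
  Feature-wise standardization uses the batch-size-weighted grand mean and
  the pooled residual variance around batch means; γ/δ² are shrunk toward
  across-feature moment-matched priors by the usual iterative solution
  (tolerance 1e-4). Parameters are estimated on discovery only and applied
  to any cohort; unseen batches are rejected. With a single feature the
  hyper-priors are undefined and the raw batch estimates are used. On fit
  data the implementation matches the reference EB implementation to ~1e-14.
  Note the EB residual: after harmonization the *systematic* batch gap is
  ~0, but each feature retains sampling noise of order √(2/n)·SD — the
  correct reading of "the shift is removed".
* **Leakage control by construction**: standardization
  (`fit_standardization()`), imputation (discovery medians), ComBat and the
  LASSO all take discovery data only and return parameter objects that are
  *applied* to validation rows; mutation tests assert that perturbing
  validation rows changes no fitted parameter, selection, or threshold.

## 6. Signatures and evaluation

Eleven candidate sets: radiomics (screened features), visual, clinical, BAT
(the score alone, no fitting), the four combined sets, and three
"select radiomics" variants that re-fit using only the features the
radiomics signature selected (a two-stage fit mitigating the dimensionality
imbalance). `fit_signature()` uses `glmnet::cv.glmnet` with internal
re-standardization disabled (inputs are already discovery-standardized;
binary markers enter as 0/1), deterministic HE-stratified 10-fold
assignment from the run seed, no class weights, and λ at the minimum mean
CV binomial deviance over a 60-value path down to 0.01·λ_max (dense enough
that the minimum is interior in practice; both the rule and the path are
configurable). The stored CV AUC is the mean ± SE of test-fold AUCs of the
prevalidated scores at the chosen λ.

Evaluation: AUC as the Mann–Whitney statistic (ties ½) with DeLong
structural-component variance and `qnorm(0.975)` CIs clipped to [0, 1];
paired DeLong z-tests (zero-variance difference with equal AUCs → p = 1);
threshold = the largest cutoff with discovery recall ≥ 0.8 (maximizing
specificity among qualifying cutoffs), reused on validation; NPV of an
all-positive rule is 1 by convention and precision of an all-negative rule
0; Spearman ρ versus mRS with midranks, Fisher-z CI with variance
1.06/(n−3) and a t-approximate p-value, missing mRS excluded with counts
reported (constant scores → missing ρ).

## 7. Problem sizes and runtime choices

The package's own studies use a `compact_cohort_spec()` preset — lesions
mean 1.7 cm³ on 0.9 mm in-plane grids with thin-slice levels
(1.5/2.5/3.5 mm) — which keeps a full two-cohort study of 900 patients,
including 1,130-feature extraction, under ~3 minutes per seed on one CPU
while exercising every stage identically to the full-size spec. The
acceptance suite runs the signal-recovery study at 2 × 450 patients over 4
seeds (observed seed means ≈ 0.60–0.67 around the 0.65 dial), the DeLong
null calibration at 1,000 replicates of n = 300, and the oracle-equivalence
sweep over 20 random ≤ 16³ volumes. Stability ICC uses a 30-patient
discovery subsample with two 1 mm-jitter replicates — the screening
statistic stabilizes quickly and a full-cohort repeat extraction would
triple the imaging cost for no inferential gain.

## 8. Known limitations

* Mesh-derived shape features follow this package's anti-aliased
  marching-tetrahedra convention; other toolkits' binary-mesh conventions
  give systematically larger areas.
* Derivative-image discretization reuses the HU bin width 25; very smooth
  sub-bands can collapse to few gray levels, where the degenerate-case
  conventions apply (this mirrors common practice, and such features are
  typically removed by the stability filter).
* The synthetic clinical variables are independent of the latent lesion
  (only markers and mRS are linked), so clinical signatures are expected to
  be uninformative in synthetic studies — by design, not a claim about real
  cohorts.
* ComBat rejects batches unseen at fit time; real deployments with new
  scanner protocols would need refitting, mirroring the fit-on-discovery
  design.
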