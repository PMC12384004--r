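---
title: "Predicting abnormal lung diffusing capacity from 4DCT parenchymal texture: models and methods"
author: "dlcoRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting abnormal lung diffusing capacity from 4DCT parenchymal texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

DLCO — the diffusing capacity of the lungs for carbon monoxide —
summarizes gas exchange across the alveolar-capillary membrane. It is
dichotomized clinically: values between 75% and 140% of predicted are
normal, anything outside is abnormal (this package treats both
boundaries as inclusive; the rule itself does not say, and the choice
only affects values exactly at the limits). Patients planned for lung
stereotactic radiotherapy always receive a respiration-correlated (4D)
CT, so the question this pipeline operationalizes is whether texture of
the healthy parenchyma on two extreme respiratory phases — maximum
inhalation (Phase 0) and maximum exhalation (Phase 50) — carries enough
signal about lung microstructure to predict the DLCO class, alone or on
top of a clinical covariate.

The region of interest is deliberately the *healthy* lung: both lungs
minus every gross tumor volume (GTV) expanded by 0.5 mm. At typical CT
resolution (1 × 1 × 2.5 mm) a 0.5 mm expansion moves no voxel centre
and is a geometric no-op; the operation is implemented generically in
physical units anyway, so finer-resolution data behave correctly.

## Preprocessing

**Intensity normalization.** Each scan's intensities at a fixed set of
anchor percentiles are mapped piecewise-linearly onto the corresponding
intensities of a designated reference scan; beyond the outermost
anchors the terminal segment slope extrapolates. The anchor set
defaults to (1, 5, 25, 50, 75, 95, 99): it brackets the distribution
while staying robust to single-voxel tails. The map is monotone by
construction, so voxel ordering — and hence every rank-based statistic —
is preserved. The histogram is fitted on the full volume by default
(an optional mask restricts it); in the pipeline the reference is the
first patient's Phase 0 scan. Normalization can be disabled for
HU-calibrated inputs; the default keeps it on, matching the procedure
the pipeline reproduces.

**Discretization.** Texture matrices need integer gray levels. We use
absolute (fixed bin width) discretization with 25 HU bins,
`level = ⌊x/W⌋ − ⌊min_mask/W⌋ + 1`, which is anchored to absolute HU
bin edges: shifting a whole region by an exact multiple of W leaves the
level grid unchanged. Filtered images reuse the same 25 HU width on
their own intensity range — a single consistent rule rather than a
per-image adaptive one, at the cost that narrow-range subbands (e.g.
`wavelet-HHH`) occupy few levels.

## Filter bank

* **Wavelet.** A single-level separable *undecimated* 3D transform with
  the Coiflet-1 filter pair and periodic boundary handling, yielding
  eight shape-preserving subbands `LLL … HHH` (letter = low/high pass
  per axis, in axis order). The analysis filters are scaled by 1/√2 so
  that |H|² + |G|² = 1 per axis; the transform then conserves energy
  exactly and correlating each subband with its own filters inverts it
  to machine precision — both properties are asserted in the tests.
  The family and level are configuration; Coiflet-1 single-level is the
  convention of the standard radiomics extraction stack, which keeps
  subband feature names comparable.
* **Laplacian of Gaussian** at physical scales (default 2 mm, forced by
  the conventional feature naming, plus a coarser 4 mm band). Per-axis
  sigma is `sigma_mm / spacing`; second-derivative kernels are sampled,
  forced to zero sum (constants map exactly to zero) and scaled to
  mm⁻²; boundaries replicate. Sub-voxel sigmas are computed but warned
  about.
* **Gradient magnitude** by central differences over physical spacing,
  one-sided at faces.
* **Intensity transforms** square, square root, logarithm, exponential
  with the standard radiomics shift/scale conventions (with
  M = max|x|): x²/M; sign(x)·√(M|x|); sign(x)·M/log(M+1)·log(|x|+1);
  exp(log(M)/M·x). All are finite for any finite input, negative HU
  included, and square∘squareroot recovers |x| exactly.

## Texture features

Beyond first-order statistics (maximum, median, mean, minimum, range,
population variance, skewness, energy) of the *undiscretized* masked
intensities, three gray-level matrices are built on the discretized
region:

* **GLCM** — co-occurrences over the 13 unique 3D directions at
  Chebyshev distance 1, restricted to in-mask pairs, symmetrized,
  pooled across directions by summation before normalization (a
  per-direction-normalize-then-average switch exists; pooling by sum is
  the default because it weights directions by their pair counts).
  Features: Correlation and the first informational measure of
  correlation (Imc1, log base 2). Degenerate single-level regions
  return Correlation = 1 and Imc1 = 0, the conventional limits of the
  standard extraction stack.
* **GLDM** — a voxel of level i has dependence j = 1 + the number of
  its 26-neighbours (out-of-mask excluded) whose level differs by at
  most α = 0. Feature: Low Gray Level Emphasis, Σ P(i,j)/i² / Nz.
* **GLSZM** — zones are 26-connected components of equal level.
  Feature: Size Zone Non-Uniformity Normalized, Σⱼ(Σᵢ P(i,j))² / Nz².

Every matrix build asserts its count-conservation invariant, and every
feature is tested against an independent brute-force enumeration oracle
on random 4×4×4 masked grids to 10⁻⁹.

∆-phase features are Phase 0 minus Phase 50 (the design only says
"difference"; the orientation is fixed here and models are invariant to
it up to coefficient sign).

## Feature selection

Screening first removes near-zero-variance columns (constant, or
most-common/second-most-common frequency ratio > 19 with distinct-value
fraction < 0.1 — the widely used convention, since the procedure itself
fixes no numbers) and then prunes pairs with |Spearman ρ| > 0.95,
dropping the member less associated with the abnormal label, visiting
pairs greedily by descending correlation so the result is deterministic
and order-free.

The selector proper iterates: build a graph on the surviving features
with edges where |ρ| > 0.75, take connected components as clusters,
keep per cluster the feature with the smallest two-sided Wilcoxon
rank-sum p-value against the abnormal-DLCO label (exact when both
groups have ≤ 10 patients and no ties; otherwise the tie-corrected
normal approximation with continuity correction), and repeat until no
edge remains. Connected components are the one parameter-free reading
of "cluster at ρ > 0.75" that makes the stopping rule (*all pairwise
|ρ| < 0.75*) exact, which is why they were chosen over hierarchical
linkage with a cut. Absolute correlation is used throughout:
anti-correlated features are equally redundant. Equal p-values break
toward the lexicographically smallest canonical name, making builds
reproducible under column permutations. Association uses baseline
labels by default (using post-treatment labels where available is a
configuration switch; baseline-only keeps the selected set identical
across endpoints, which mirrors how the score models are reused).

Each iteration with at least one edge strictly reduces the feature
count, so termination is guaranteed; the audit trail records clusters,
p-values and winners per iteration plus the counts surviving each
screening step.

## Radiomic score and the thirteen models

LASSO logistic regression on the standardized selected features gives
one coefficient per feature; the penalty is chosen at the minimum of a
seeded, stratified internal cross-validated deviance over a 50-value
path (the procedure being reproduced fixes no tuning rule; a fixed
`lambda` can be supplied instead). The radiomic score of a patient is
the intercept-free weighted sum Σ βⱼxⱼ; downstream logistic models
refit an intercept (and the clinical coefficient) on top of it.

Thirteen model specifications are evaluated: {radiomic,
clinical-radiomic} × {Phase 0, Phase 50, ∆} × {baseline,
post-treatment} plus a single clinical model (CCI by default) at
baseline. Post-treatment models reuse the planning-time imaging
features — only the endpoint label changes — because imaging is
acquired at simulation only.

**Evaluation.** Repeated stratified 3-fold cross-validation (default
100 repetitions; the acceptance runs use 50). Stratification is needed
because the post-treatment minority class is small. *Everything
learned is learned inside training folds*: screening, clustering
selection, standardization parameters, LASSO coefficients and the
logistic refit; held-out predictions are pooled into one AUC (rank
form, ties counted half) per repetition, summarized as median and IQR.
A permuted-label canary in the test suite confirms the absence of
leakage: with labels permuted, the strongly separable synthetic cohort
yields chance-level cross-validated AUC. When a LASSO fit shrinks every
coefficient to zero the score is constant and the fold predicts the
intercept — AUC 0.5 by the tie convention, which is exactly the honest
null behaviour.

Univariate statistics accompany the models: Wilcoxon rank-sum for
continuous covariates, Pearson χ² for categorical ones switching to
Fisher's exact test when any expected cell is ≤ 5, and the exact (n ≤
25) two-sided Wilcoxon signed-rank test for paired baseline/post DLCO
values (all differences zero returns p = 1 by convention).

## The synthetic cohort

The generator exists because the clinical cohort is unavailable; it
emulates the statistical structure the analysis assumes, not anatomy.
Defaults encode the study conditions: abnormal-baseline fraction 55/98,
post-treatment availability 24/98, 48×48×32 voxels at 1×1×2.5 mm.

Per patient: the lung is an ellipsoid (semi-axes 42% of the grid
extent); parenchyma is a Gaussian random field — white noise smoothed
with a Gaussian kernel — with latent per-patient parameters

* correlation length: 2 mm × (1 + 0.5·effect in the abnormal class),
* mean attenuation: −850 HU (+ 30·effect HU if abnormal),
* field spread: 60 HU × (1 + 0.3·effect if abnormal),

each jittered log-normally/normally between patients so that at
`textureEffect = 1` the class separation in each latent is roughly
twice its within-class spread. These three latents were chosen as the
smallest set that moves the three feature families the analysis
selects: spatial correlation (GLCM Correlation), gray-level composition
(GLDM Low Gray Level Emphasis) and the intensity distribution
(first-order statistics). Lesions are soft-tissue (≈ 20 HU) spheres
with radius 4–8 mm placed uniformly inside a proportionally shrunk
ellipsoid, which guarantees full containment in the lung, so the
lungs-minus-GTV subtraction is always exercised. Phase 50 is the
noiseless Phase 0 content compressed craniocaudally by the factor
`phaseCompression` (default 0.85) with linear slice resampling, plus
independent 20 HU acquisition noise per phase — so ∆ features are
non-zero and class-informative without a deformable-registration
dependency. Masks are defined on Phase 0 geometry and shared by both
phases; near the lung poles the compressed phase therefore samples
body-density tissue, an intended (atelectasis-like) part of the ∆
signal. DLCO percentages come from truncated normals — normal class
centred at 95% on [75, 140], abnormal at 60% below 75 — and the label
is re-derived through the 75–140 rule so value and label can never
disagree. CCI is Poisson(2 + clinicalEffect in the abnormal class);
COPD and smoking prevalences shift on the logit scale with the same
knob; age is truncated-normal around 70.

What the generator does **not** emulate: real anatomy (two lung lobes,
airways, vessels), scanner-specific noise texture and artifacts,
DICOM/RTSTRUCT provenance, deformable respiratory motion, or any true
biological link between parenchymal texture and gas exchange. Passing
tests therefore demonstrate that the pipeline recovers structure *of
the kind it assumes* and is calibrated under its null — not that the
clinical effect sizes are reproducible.

Note one interaction worth knowing: histogram normalization aligns
marginal intensity distributions across patients, which deliberately
mutes the planted mean/spread signal on the *original* image; class
signal then survives through spatial structure (GLCM Correlation) and
through filtered-image statistics, which is also where the reproduced
analysis found its features.

## Numerical choices and degenerate inputs

* Degenerate (constant) images are flagged and normalized to a
  constant at the reference median anchor; duplicate percentile knots
  collapse by averaging.
* Single-gray-level regions: GLCM Correlation = 1, Imc1 = 0; skewness
  of a constant sample is 0.
* All-zero-coefficient LASSO fits and constant predictors are handled
  by dropping the predictor and predicting the intercept.
* Seeds: every stochastic step (cohort generation, fold shuffles,
  internal penalty folds, permutation canaries) derives from one user
  seed through a Lehmer-style integer hash kept below 2³¹.
* The 4-feature minimum grid for texture is 2×2×2; volumes smaller
  than the wavelet filter length (6) are rejected.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full design on
synthetic cohorts of 200 patients with 50 cross-validation repetitions
(the null-calibration and signal-recovery checks), 500 simulations for
the rank-sum type-I error, and selection-recovery sweeps over 20 (tests)
or 10 (script) seeds of 30 patients each — sizes chosen to give stable
Monte-Carlo estimates on a single CPU in minutes. Oracle-equivalence
checks use 50 random 4×4×4 grids, where brute-force enumeration is
exact and fast.

## Known limitations

* The wavelet letter convention (first letter = first array axis)
  matches the package's own axis order; tools that order letters
  z-first will label subbands differently.
* GLCM direction pooling by summation weights directions unevenly near
  mask boundaries; the per-direction averaging switch exists but has
  no test oracle from the reproduced analysis.
* The clinical model is a single-covariate logistic fit by default;
  the covariate list is configurable but the reproduced design treats
  CCI as the exemplary clinical variable.
* Post-treatment endpoints at realistic availability (≈ 25%) leave few
  patients; with small synthetic cohorts those models are reported as
  NA rather than evaluated on unstratifiable folds.
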