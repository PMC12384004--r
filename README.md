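# dlcoRadiomics

CT radiomics of healthy lung parenchyma for predicting abnormal lung
diffusing capacity (DLCO).

Patients evaluated for lung stereotactic body radiotherapy receive a
respiration-correlated (4D) planning CT but often no complete pulmonary
function work-up. This package implements a pipeline that asks whether
texture of the *healthy* lung parenchyma — the lungs minus the expanded
gross tumor volume (GTV) — on two respiratory phases (Phase 0 ≈ maximum
inhalation, Phase 50 ≈ maximum exhalation) predicts whether a patient's
DLCO is abnormal, where DLCO is dichotomized by the clinical rule

    normal  ⇔  75% ≤ DLCO (% predicted) ≤ 140%.

It is aimed at researchers in quantitative imaging who want a tested,
self-contained re-implementation of this analysis design that runs end
to end on synthetic data.

## What the pipeline does

1. **Preprocessing** — histogram-based intensity normalization
   (percentile anchors of each scan linearly mapped onto a reference
   scan), absolute gray-level discretization with bin width 25 HU
   (`level = ⌊x/W⌋ − ⌊min/W⌋ + 1`), 0.5 mm geometric GTV expansion and
   lungs-minus-GTV mask subtraction.
2. **Filter bank** — undecimated single-level 3D wavelet subbands
   (coif1; `wavelet-LLL` … `wavelet-HHH`), Laplacian of Gaussian at
   physical scales (e.g. `log-sigma-2-0-mm-3D`), gradient magnitude,
   and square / square-root / logarithm / exponential intensity
   transforms.
3. **Features** — first-order statistics plus gray-level co-occurrence
   (GLCM Correlation, Imc1), gray-level dependence (GLDM Low Gray Level
   Emphasis) and gray-level size-zone (GLSZM Size Zone Non-Uniformity
   Normalized) texture features, named `filter_class_feature`; computed
   per phase, plus ∆-phase differences (Phase 0 − Phase 50). Every
   matrix feature is verified against brute-force enumeration in the
   test suite.
4. **Feature selection** — near-zero-variance screening; Spearman
   |ρ| > 0.95 redundancy pruning; then an iterative correlation
   clustering: features are grouped into connected components of the
   |ρ| > 0.75 graph and each cluster keeps only its member most
   associated with abnormal DLCO (Wilcoxon rank-sum), iterated until
   all pairwise |ρ| < 0.75.
5. **Radiomic score** — L1-penalized (LASSO) logistic coefficients on
   the selected features; the per-patient score is
   `score = Σ_j β_j · x_j` (no intercept).
6. **Thirteen models** — {radiomic, clinical-radiomic} × {Phase 0,
   Phase 50, ∆ Phase} × {baseline, post-treatment DLCO} plus one
   clinical (Charlson Comorbidity Index) model at baseline, each
   evaluated by repeated stratified 3-fold cross-validation with the
   whole learned pipeline (selection, standardization, LASSO) refit
   inside training folds, summarized as median (IQR) AUC.

Because the clinical imaging cohort behind this design is not publicly
available, the package ships a **synthetic-cohort generator**: paired
phase volumes whose parenchymal Gaussian-random-field texture
(correlation length, mean attenuation, spread) differs between DLCO
classes by a tunable effect size, spherical lesions placed inside an
ellipsoidal lung, craniocaudal compression between phases, and clinical
covariates (CCI, COPD, smoking, age) coupled to the label.

## Worked example

```r
library(dlcoRadiomics)

cohort <- generateCohort(cohortConfig(nPatients = 60, seed = 11))
cohort
#> RadiomicsCohort with 60 patients
#>   abnormal baseline DLCO: 36 / 60
#>   with post-treatment DLCO: 11 / 60

ref <- fitReferenceHistogram(cohortPatients(cohort)[[1]]@phase0)
cfg <- extractionConfig(normalizationMap = ref)
data <- cohortModelData(cohort, cfg)
dim(data$features$Phase0)
#> [1]  60 192

sel <- selectFeatures(data$features$Phase0, data$baselineLabel)
head(selectedFeatures(sel), 3)
#> [1] "exponential_firstorder_Skewness" "gradient_firstorder_Maximum"
#> [3] "gradient_firstorder_Minimum"

ev <- evaluateModels(data, reps = 10, seed = 5)
subset(ev$summary, endpoint == "baseline")[, 1:4]
#>                kind phaseDesign endpoint medianAUC
#> 1          clinical        none baseline     0.656
#> 2 clinical-radiomic       Delta baseline     1.000
#> 3 clinical-radiomic      Phase0 baseline     0.999
#> 4 clinical-radiomic     Phase50 baseline     1.000
#> 5          radiomic       Delta baseline     1.000
#> 6          radiomic      Phase0 baseline     1.000
#> 7          radiomic     Phase50 baseline     1.000
```

With the generator's default planted effect the radiomic separations
are near-perfect, so the radiomic and clinical-radiomic models reach
AUC ≈ 1 while the clinical covariate alone gives a moderate AUC — the
qualitative ordering the design is meant to exhibit. Setting
`textureEffect = 0, clinicalEffect = 0` yields chance-level (≈ 0.5)
AUCs for all thirteen models.

A YAML-driven run (simulate → extract → select → model → report) is
available through `runPipeline()` / `pipelineCli()`; see
`inst/scripts/dlco-radiomics.R` for the command-line wrapper and the
methods vignette (`vignettes/methods.Rmd`) for the modelling details.

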