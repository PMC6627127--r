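# qmripredict

Predicting the local outcome of chemoradiotherapy — local control
versus local failure — in sinonasal squamous cell carcinoma from
pre-treatment multiparametric MRI. The package is aimed at quantitative
imaging researchers who want a fully tested, reproducible
implementation of the whole analysis chain: quantitative feature
extraction from T2-weighted, arterial-spin-labeling (ASL) and
multi-b-value diffusion-weighted images, and a machine-learning
evaluation layer built around a radial-basis SVM with backward
sequential feature elimination under nested 9-fold cross-validation.

Because the patient images this analysis targets are not publicly
available, the package also ships a first-class synthetic cohort
generator calibrated to the published group statistics of a 36-patient
cohort (22 local control / 14 local failure), so that the entire
pipeline can be exercised, tested and benchmarked without any download.

## The quantities at the core

Twenty-seven features per patient:

* **Clinical**: ordinal T-stage (1–4) and N-stage (0–3).
* **Morphology** (from the tumor mask): volume *V*, surface area *A*
  from a triangulated iso-surface of the mask's signed distance
  transform, and sphericity Ψ = π^⅓(6V)^⅔ / A.
* **T2 intensity/texture**: relative mean signal (tumor / medial
  pterygoid muscle), coefficient of variation, and the Haralick GLCM
  features contrast, correlation, energy and homogeneity (G = 64
  levels, four in-plane distance-1 offsets, symmetric).
* **Perfusion**: absolute tumor blood flow from the single-compartment
  pCASL model, TBF = 6000·λ·ΔM·e^(PLD/T1b) / (2·η·M0·T1b·(1−e^(−τ/T1b))),
  with τ = 1650 ms and PLD = 1280 ms, plus relative TBF (tumor/muscle).
* **Diffusion** (12 b-values, 0–2000 s/mm²): mono-exponential ADC;
  IVIM *f*, *D\**, *D*; tri-exponential *f₁…f₃*, *D₁…D₃*;
  stretched-exponential α, DDC; kurtosis *K*, *D_k* — fitted on the
  ROI-mean signal with each model's b-value subset.

The evaluation protocol divides the 36 patients into nine random folds
of four; per fold, feature scaling, grid search over
γ = 2⁻²⁰…2¹⁰ and C = 2⁻¹⁰…2¹⁰, and backward sequential elimination
(which also yields a full feature ranking) run on the 32 training
patients only, and the refitted model is scored on the held-out four.
Sensitivity, specificity, PPV, NPV and accuracy are reported per fold
and as means.

## Worked example

```r
library(qmripredict)

# sample ground-truth records for 6 patients and render them as images
recs <- sample_cohort(n_per_group = c(4, 2), seed = 1)
pats <- synthesize_cohort(recs, acquisition_config(), seed = 1)
tbl  <- extract_cohort_features(pats)
round(tbl[1:3, c("volume_mL", "sphericity", "tbf_rel", "adc", "d2")], 3)
#>   volume_mL sphericity tbf_rel   adc    d2
#> 1    14.955      0.776   6.688 0.681 0.737
#> 2    28.357      0.689   7.906 0.734 1.274
#> 3    11.468      0.841   8.184 0.713 2.056
```

Each row is one synthetic patient: a ~10–30 mL tumor of moderate
irregularity (sphericity 0.69–0.84), perfused ~7–8× stronger than
reference muscle, with an ROI-level ADC near 0.7 × 10⁻³ mm²/s — the
scale expected for this tumor type (the ROI ADC sits below the
mono-exponential calibration value because the generated decay is
tri-exponential, and the d2 column shows the noise sensitivity of the
intermediate tri-exponential compartment discussed in the vignette). On a full 36-patient cohort the
classification experiment runs as

```r
recs <- sample_cohort(seed = 1)                       # 22 control / 14 failure
pats <- synthesize_cohort(recs, acquisition_config(), seed = 1)
tbl  <- extract_cohort_features(pats)
res  <- run_experiment(tbl, svm_config(), seed = 1)   # ~2 min
res
#> <cv_experiment: 9 folds, seed 1>
#> mean training metrics:
#> sensitivity specificity         ppv         npv    accuracy
#>       0.944       0.994       0.992       0.970       0.976
#> mean validation metrics:
#> sensitivity specificity         ppv         npv    accuracy
#>       0.500       0.935       0.714       0.778       0.750
#> most selected features:
#>    sphericity       tbf_rel   surface_cm2       tbf_abs     volume_mL
#>             9             9             7             7             7
```

Tumor sphericity and relative TBF are selected in every fold, with
tumor volume and contrast close behind — the same feature families
that dominate in the clinical study this pipeline reproduces. A
command-line wrapper with `simulate`, `extract-features` and
`train-eval` subcommands is installed under
`system.file("exec", "qmripredict-cli", package = "qmripredict")`.

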