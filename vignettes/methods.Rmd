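---
title: "Methods: quantitative MRI features and nested SVM outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative MRI features and nested SVM outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`qmripredict` implements an end-to-end pipeline for predicting the local
outcome (control versus failure) of chemoradiotherapy in sinonasal
squamous cell carcinoma from pre-treatment multiparametric MRI: 27
quantitative features per patient — clinical T-/N-stage, tumor shape,
T2 intensity and texture, ASL perfusion, and five families of
multi-b-value diffusion parameters — feed a radial-basis SVM with
backward sequential feature elimination, evaluated under a nested
9-fold cross-validation. Because the clinical images the pipeline
targets are not publicly available, the package ships a first-class
synthetic cohort generator whose feature distributions are calibrated
to the published group statistics of a 36-patient cohort (22 local
control, 14 local failure); every stage of the pipeline is exercised
and tested against that generator.

# Diffusion models

Signals are modeled on the 12-value b-schedule
0, 10, 20, 30, 50, 80, 100, 200, 400, 800, 1000, 2000 s/mm² with
coefficients carried in the conventional ×10⁻³ mm²/s units:

* mono-exponential: $S(b) = S_0 e^{-b\,\mathrm{ADC}}$
* IVIM (bi-exponential): $S(b) = S_0[f e^{-b D^*} + (1-f) e^{-b D}]$
* tri-exponential: $S(b) = S_0 \sum_{i=1}^3 f_i e^{-b D_i}$, $\sum f_i = 1$,
  $D_1 > D_2 > D_3$
* stretched exponential: $S(b) = S_0 e^{-(b\,\mathrm{DDC})^\alpha}$
* kurtosis: $S(b) = S_0 e^{-b D_k + b^2 D_k^2 K/6}$

IVIM and the tri-exponential model are fitted on all 12 b-values;
ADC, SEM and DKI on the reduced subset {0, 200, 400, 800, 1000, 2000}
s/mm², where perfusion-related signal has decayed.

Fitting choices (the source the pipeline reproduces does not print its
optimizer, so these are the package's own, stated choices):

* ADC is a log-linear regression (closed form). DKI is also solved in
  closed form, because $\log S$ is linear in $(b, b^2)$.
* IVIM and the tri-exponential model are fitted in a cascaded fashion —
  slow compartments from the high-b segment first, perfusion from the
  low-b excess — followed by a bounded joint Levenberg–Marquardt
  refinement (`minpack.lm`) with three jittered starts under a fixed
  internal seed. Raw joint fits of tri-exponentials are ill-conditioned;
  the cascade provides starts inside the basin of attraction.
* Bounds: $f \in [0,1]$, $D^* \in [3,300]$, $D \in [0.05,3]$,
  $D_1 \in [3,300]$, $D_2 \in [0.3,3]$, $\alpha \in (0.3,1]$,
  $K \in [0,3]$ (×10⁻³ mm²/s where applicable). The simplex constraint
  of the tri-exponential fractions is parameterised as
  $f_2 = q(1-f_1)$, $f_3 = (1-q)(1-f_1)$ and the slow coefficient as a
  ratio $D_3 = r D_2$, $r \in [0.05, 0.92]$, so that the box constraints
  imply the ordering structurally.
* A non-converged fit never throws: the best parameters so far are
  returned with `converged = FALSE`.
* The package fits the ROI-mean signal (one parameter set per tumor),
  matching the single-ROI parameters the target study reports; the
  per-voxel route would be noise-dominated at these voxel sizes.

# ASL perfusion

Tumor blood flow is quantified from the control-minus-label subtraction
signal with the consensus single-compartment pCASL model

$$\mathrm{TBF} = \frac{6000\,\lambda\,\Delta M\,e^{\mathrm{PLD}/T_{1b}}}
{2\,\eta\,M_0\,T_{1b}\,(1 - e^{-\tau/T_{1b}})}$$

with labeling duration $\tau$ = 1650 ms and post-label delay
PLD = 1280 ms from the acquisition protocol, and defaults
$\lambda$ = 0.9 mL/g, $T_{1b}$ = 1650 ms (3 T), $\eta$ = 0.85 — all
configurable. The control image serves as the $M_0$ proxy (the protocol
acquires no separate $M_0$ scan). The exact constants of the original
quantification are not published; the synthetic ASL generator therefore
uses the same forward equation, making absolute-flow recovery a closure
property that holds for any constant choice, and relative TBF (tumor
flow divided by medial pterygoid muscle flow) is additionally invariant
to global scanner gain.

# Morphology

Volume is voxel count × voxel volume. Surface area is measured on a
triangulated iso-surface: the binary mask is converted to a signed
Euclidean distance transform (exact separable algorithm, anisotropic
spacing honored), lightly smoothed (0.6 voxel), and triangulated by
marching tetrahedra at level zero; sphericity is
$\pi^{1/3}(6V)^{2/3}/A$. The distance-transform field was chosen over
the raw binary indicator because a triangulation of the binary mask
overestimates the area of digital balls by ≈20–27 % (staircase effect),
which would systematically depress sphericity; the smoothing scale 0.6
voxel balances residual staircase error on curved surfaces (≈ +2 %)
against corner rounding on polyhedral shapes (≈ −2.5 %), verified
against closed forms (ball, cube, anisotropic ball) in the test suite.

# T2 intensity and texture

Relative mean signal is tumor ROI mean divided by muscle ROI mean; CV
is SD/mean in the tumor. Texture uses Haralick features (contrast,
correlation, energy, homogeneity) on a gray-level co-occurrence matrix
accumulated slice-wise in 2D over the four distance-1 offsets,
symmetric, min–max quantized to G = 64 levels within the ROI, matrices
summed over slices and offsets before normalisation. The convention
(2D offsets, distance 1, G = 64) is not printed in the source study;
G = 64 is consistent with the published energy scale (≈1.5 × 10⁻³,
close to the correlated-field value at 64 levels) and everything is
configurable. A constant ROI is degenerate by convention: contrast 0,
correlation 0 (flagged), energy 1, homogeneity 1. Necrotic or cystic
voxels flagged in a sidecar mask are excluded from every ROI statistic
across all sequences.

# Synthetic cohort

`sample_cohort()` draws per-patient ground-truth records from
group-conditional independent Gaussians with the published means and
SDs (only marginals are published; a correlation-matrix hook exists),
truncated to physical ranges: tri-exponential fractions clipped to
[0.01, 0.97] and renormalised to sum 1, diffusion coefficients floored,
$\alpha \le 1$, $K \ge 0$. T-/N-stages are drawn from the published
contingency counts. Image synthesis then realizes each record:

* **Shape** — a star-shaped blob (random ellipsoid with 32 smooth
  radial bumps, deformation bounded to the [0.3, 1.9] radial band) is
  calibrated by root finding so its continuum sphericity matches the
  target, scaled to the target volume and voxelized per sequence grid
  (mirroring per-sequence ROI delineation). Targets below the shape
  family's reachable minimum (≈0.5, seed-dependent) are clamped.
* **DWI** — tumor voxels follow the tri-exponential forward model (the
  richest model, so the four simpler models are exercised on
  realistically mis-specified decays); background is mono-exponential.
  Rician magnitude noise at b0-SNR 50 (typical for 3 T head/neck EPI;
  the source is silent) is applied per signal average with the
  protocol's averaging scheme (1× for b ≤ 100, 2× for 200–800, 3× for
  1000–2000).
* **ASL** — ΔM generated by the quantification equation above plus
  Gaussian noise; control carries tissue $M_0$.
* **T2** — tumor voxels are a spatially correlated Gaussian field,
  standardized exactly within the ROI so relative mean and CV are met
  exactly; the correlation length is calibrated by bisection against
  the measured GLCM contrast.

**Realized ground truth.** Some features cannot be dialed
independently at the image level: surface area follows from volume and
sphericity (the three published shape means are mutually inconsistent
with the sphericity formula — sphericity computed from the printed
mean volume and surface is 0.83, not 0.71); GLCM correlation, energy
and homogeneity emerge from the Gaussian-field model once contrast is
set; and the ADC/IVIM/SEM/DKI parameters of a tri-exponential decay
are deterministic projections rather than free parameters. Each
patient therefore carries two records: the *sampled* record (used for
population calibration, which holds for all 27 marginals) and the
*realized* record, in which these derived entries are replaced by
their noiseless image-level values. The noiseless extraction
round-trip is exact against the realized record; estimator accuracy is
validated separately against analytic shapes and forward models. The
tri-exponential compartments are sorted ($D_1 > D_2 > D_3$) before
image generation because fitted compartments are magnitude-ordered;
the sampled marginals are left unsorted to preserve calibration.

What the generator does **not** emulate: anatomy, k-space/EPI
artifacts, motion, partial-volume mixtures at tumor borders,
within-patient feature correlations (not published), and any coupling
between diffusion and perfusion compartments. Passing tests on this
cohort therefore demonstrate correctness of the computational
pipeline, not clinical performance on real images.

# SVM engine

Features are z-scored with scalers fitted on each training fold only.
The classifier is an RBF-SVM (`e1071`); the positive class is local
failure. Hyperparameters are chosen by exhaustive grid search over
$\gamma = 2^{-20} \ldots 2^{10}$, $C = 2^{-10} \ldots 2^{10}$ (integer
exponents), scored by stratified 4-fold inner cross-validation on the
training fold, ties broken toward smaller $C$ then smaller $\gamma$.

Backward sequential elimination starts from all 27 features; each
iteration refits with every single remaining feature left out and
permanently removes the one whose omission scores best, down to a
single feature; the elimination iteration defines the feature ranking.
Because inner-CV accuracy on 32 patients is quantized in steps of
1/32, ties are frequent; they are broken by the mean signed decision
margin of the same inner-CV predictions (bounded to stay below the
accuracy quantum), then by fixed feature order. The final subset is
the smallest top-k prefix of the ranking with the highest inner-CV
accuracy, with the prefix scores re-estimated on `select_reps = 10`
repeated inner partitions (the subset choice is the step most exposed
to selection noise). The final model is re-tuned by grid search on
the selected subset and refitted on the full training fold.

The outer evaluation divides the 36 patients into 9 random folds of 4
(unstratified by default, matching a plain random division; a
stratified option exists). Each fold's held-out patients touch neither
the scaler, the grid search nor the elimination — enforced by an
instrumentation test that poisons held-out labels and verifies the
trained models are bit-identical. Reported metrics are sensitivity,
specificity, PPV, NPV and accuracy per fold and as means over folds
(ratios with zero denominators are flagged and excluded from the
mean); selection frequencies across folds summarize which features the
protocol favors.

# Problem sizes and numerical choices

The default synthetic geometry is tumor-centric: T2 at 1.5 mm
isotropic (48³ grid, enlarged automatically for large tumors), DWI at
the protocol's 3.59 × 3.59 × 5 mm, ASL at 2.875 × 2.875 × 5 mm. A
1 mm isotropic grid is used for the shape-fidelity tests. The test
suite runs the full image-level pipeline on a 36-patient cohort and a
label-permutation null on reduced hyperparameter grids with
elimination disabled (chance-level accuracy under the null does not
depend on the grid); Monte-Carlo suites use 50–60 replicates. The
Bayes-rate reference for the classification analogue is estimated by
classifying 2 × 10⁴ sampler draws with the exact group likelihoods of
the generating distributions; because the generator samples the 25
continuous features independently, this oracle (≈0.97 accuracy) is an
upper bound that no 32-patient training procedure is expected to
reach, which is why the analogue asserts accuracy against the oracle
minus a 0.10 margin.

# Known limitations

* The published equations of the original in-house implementation
  (diffusion fitting, ASL constants, GLCM convention, inner selection
  protocol) are not printed; the package adopts the standard published
  forms and states every choice above. Recovery targets are therefore
  self-consistency and closure properties, not bit-matches.
* Backward elimination with inner-CV scoring on 32 patients remains a
  high-variance selector; on the synthetic cohort it costs a few
  accuracy points relative to using all features, and the package
  reports both (set `eliminate = FALSE` to compare).
* The sphericity estimator is accurate to ≈±2–3 % at the default
  grids; digital shapes much smaller than ~50 voxels are rejected.
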