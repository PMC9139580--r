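---
title: "Methods: phantom simulation, tracer kinetics, and the spatiotemporal classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom simulation, tracer kinetics, and the spatiotemporal classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpcore)
```

## Overview

`ctpcore` studies a simple clinical question end to end: can a neural network
classify stroke patients into *small* versus *large* ischemic core directly
from slice-reduced CT-perfusion (CTP) stacks, bypassing the conventional
tracer-kinetic analysis that normally produces core volumes? The package
contains everything needed to pose and test that question without clinical
data:

1. a seeded digital CTP phantom with exact tracer-kinetic ground truth,
2. the conventional analysis chain (AIF selection, deconvolution,
   CBV-threshold core volumetry, median dichotomization) used for labeling,
3. preprocessing onto a standardized grid (temporal interpolation, in-plane
   resampling, rigid co-registration),
4. a two-slice spatiotemporal convolutional classifier, and
5. a cross-validation harness with early stopping, fold ensembling, ablation
   arms and ROC analysis.

This vignette records the modeling choices, their rationale, and the limits
of what the synthetic experiments can show.

## Tracer-kinetic model

Indicator-dilution theory links the arterial input function (AIF) $c_a(t)$
and the tissue concentration $C(t)$ of a voxel through

$$C(t) = \frac{\mathrm{CBF}}{6000}\,(c_a \ast R)(t), \qquad
  R(t) = e^{-t/\mathrm{MTT}},$$

where CBF is in mL/100 mL/min (the factor $1/6000$ converts to a per-second,
per-unit-volume rate), CBV in mL/100 mL, MTT in seconds, and the central
volume principle ties them together as $\mathrm{MTT} = 60\,\mathrm{CBV} /
\mathrm{CBF}$. Integrating the convolution gives the mass-conservation
identity $\int C = (\mathrm{CBV}/100)\int c_a$, which the package uses both
as a CBV estimator and as a correctness oracle for the simulator.

Choices worth recording:

* **AIF form.** A gamma variate $c_a(t) \propto (t-t_0)^{\alpha}
  e^{-(t-t_0)/\beta}$ with $t_0 = 6$ s, $\alpha = 3$, $\beta = 1.5$ s,
  peak-normalized. This is the standard parametric first-pass bolus model;
  clinical studies measure the AIF rather than assume a form, so the specific
  parameters are a simulation choice: they give a realistic ~10 s
  time-to-peak and a bolus that has fully passed within a 48 s scan.
* **Residue function.** Mono-exponential — the simplest residue consistent
  with the central volume principle ($\int R = \mathrm{MTT}$). No
  recirculation and no arterial delay/dispersion are simulated, which keeps
  the deconvolution stage exactly verifiable.
* **Discrete convolution.** Trapezoid quadrature, not the rectangle rule.
  The rectangle rule biases $\int C$ by a factor
  $\approx 1 + \Delta t/(2\,\mathrm{MTT})$ (about +19% for gray matter at
  $\Delta t = 1.5$ s), violating mass conservation on any practical grid;
  with trapezoid weights the identity holds to $\sim 10^{-5}$ relative error
  on a 0.05 s grid and to ~1% at the 1.5 s scan resolution.
* **Arterial voxels carry the input itself.** A large-artery voxel is the
  *source* of the input function, not a perfused tissue compartment, so the
  phantom renders vessel voxels with the AIF curve directly (nominal
  CBV-100 surrogate kinetics in the truth maps). Deconvolving a curve by
  itself then correctly yields $\int k = 1$, i.e. CBV = 100 mL/100 mL, and
  the measured AIF equals the true one — rendering the artery as a 1 s-MTT
  tissue compartment instead would distort its discrete area by ~18% at
  1.5 s sampling and bias every CBV estimate downstream.

## The digital phantom

Each sample is a two-slice, 32-frame, 128×128 stack over a 200×200 mm²
field of view (1.5 s frame spacing, 48 s scan) — the standardized grid of the
preprocessing stage. Anatomy is deliberately minimal: an elliptical brain
(semi-axes 75×90 mm) with a gray-matter ribbon (CBF 60, CBV 4), a
white-matter core (CBF 25, CBV 2), a 2×2-voxel arterial block per slice, and
10 mm slice thickness, roughly the two ASPECTS-level slices a radiologist
would select. HU conversion is linear (`hu_per_conc = 350`, ~8 HU peak
gray-matter enhancement, ~350 HU arterial peak; baselines gray 35, white 25,
vessel 45, background 0 HU). Degradations are additive Gaussian HU noise
(default σ = 1) and per-frame integer-pixel rigid shifts.

An ischemic lesion is an ellipse spanning both slices whose voxels keep
their tissue class but have CBF and CBV multiplied by factors below one
(defaults 0.3 / 0.25), with MTT recomputed so the central volume identity
stays exact. With the default scales, lesion CBV falls below the
1.2 mL/100 mL operational core threshold in both tissue classes, so the true
core is the full lesion. Two lesion-size laws are provided:
`lesion_law_uniform()` (semi-axes 4–26 mm, a continuous spread of core
volumes, the default cohort) and `lesion_law_separated()` (4–7 mm versus
18–24 mm modes — the "strongly separated" condition used for learnability
experiments). Cohort labels dichotomize true core volume at the cohort
median; a volume exactly at the median is labeled *large* (the defining
inequalities are strict on both sides, so the tie needs a rule; ties cannot
occur with continuous laws).

What the phantom does **not** emulate: realistic anatomy or texture, partial
volume effects, beam hardening, recirculation, penumbra (a CBF-reduced but
CBV-preserved rim), arterial delay/dispersion, or vendor-specific map
calibration. Tests passing on phantoms therefore certify the *machinery* —
kinetics, geometry, bookkeeping, optimization — not clinical performance.

## Conventional analysis (the labeling oracle)

The kinetic chain mirrors standard CTP post-processing:

* **Concentration.** $C(t) = (\mathrm{HU}(t) - \text{baseline})/k$ with the
  baseline averaged over the first 3 pre-bolus frames. All derived
  parameters are ratios, so the HU conversion factor cancels.
* **Brain mask.** Baseline HU > 5 (phantom background is 0 HU).
* **AIF selection.** The masked voxel with the highest peak concentration;
  ties break by earliest time-to-peak, then lowest (row, column) index. The
  phantom's vessel-supremacy property guarantees this finds the arterial
  block.
* **Deconvolution.** Truncated SVD of the lower-triangular Toeplitz AIF
  matrix (trapezoid quadrature, scaled by $\Delta t$), solving
  $C = A k$ for $k(t) = \mathrm{CBF}\,R(t)/6000$ per voxel. CBF
  $= 6000 \max_t k(t)$; CBV $= 100 \int C / \int c_a$ (trapezoid with
  negative lobes clipped — deliberately independent of the deconvolution, so
  CBV accuracy does not depend on the truncation level); MTT
  $= 60\,\mathrm{CBV}/\mathrm{CBF}$; TTP $= \arg\max_t C(t)$.
* **Truncation level.** Default 0.005 of the largest singular value for
  noiseless/lightly-filtered data; ~0.2 is appropriate for noisy data. On
  noiseless phantoms at the 1.5 s scan grid this recovers voxel CBF within
  0.2% and CBV within 1.7%; a 0.05 truncation — a common choice for noisy
  clinical data — already clips real signal components here and biases CBF
  low by ~15–30%, which is why the noiseless default is smaller.
* **Core volumetry.** Core = voxels with CBV < 1.2 mL/100 mL inside the
  brain mask; volume = voxel count × voxel volume; cohort labels dichotomize
  at the median core volume.

No block-circulant (delay-insensitive) deconvolution variant is provided:
the simulator has no arterial delay, so the plain Toeplitz form is the
correct oracle, and delay-insensitive variants are listed as out of scope.

## Preprocessing

* **Temporal interpolation** is linear, per voxel, onto the
  1.5 s / 48 s / 32-frame grid. Sources that do not cover the target span
  raise an error (mirroring the exclusion of non-interpolatable
  acquisitions); longer sources are truncated.
* **In-plane resampling** is bilinear onto 128×128 pixels spanning a
  centered 200×200 mm² field of view, with pixel-center coordinates and
  0-based frame times. Resampling an image already on the target geometry is
  an exact identity.
* **Co-registration** aligns every frame to the frame at t = 0 with a 2D
  rigid transform (translation + rotation) minimizing the mean squared
  error, estimated jointly over both slices (head motion moves the slices of
  one frame together). Initialization is FFT cross-correlation over integer
  shifts, followed by Nelder-Mead refinement. If refinement cannot improve
  on the unregistered frame the identity is kept, so the metric never
  degrades. The registration model matches the simulator's motion model
  (integer translations) by design, making recovery exactly checkable; the
  rotation channel is exercised by the refinement stage.

## The classifier

Each of the two slices feeds a submodel of identical architecture with
independent weights:

1. **Spatial extractor, shared over time.** Every frame passes through the
   same convolutional backbone; global average pooling over the final
   feature maps yields one feature vector per frame, giving a
   `n_frames × feature_dim` matrix per slice (32 × 512 in VGG19 mode).
   Global pooling is the natural shape-consistent reduction for 128×128
   inputs.
2. **Temporal extractor.** Two parallel pathways — a *global* 1D
   convolution (3 filters, kernel 11) and a *local* one (kernel 3) — each
   followed by global max pooling over time; outputs are concatenated and
   passed through a 32-unit dense layer (ReLU). The 1D convolutions are
   linear: the global max over time supplies the nonlinearity, and a ReLU
   in front of a global max could permanently silence a filter (with only
   three filters per pathway that is a real risk).
3. **Fusion head.** The two 32-vectors are concatenated and fully connected
   to a single sigmoid unit giving the large-core probability.

Backbones: `"vgg19"` implements the VGG19 convolutional stack (feature
dimension 512; single-channel frames are replicated to its three input
channels; ImageNet weights can be supplied as a converted parameter list but
are not required, and random initialization is the default). `"tiny"` is the
desk-scale backbone used throughout the tests: a fixed average-pooling stem
(default factor 8, i.e. a 16×16 working grid for 128×128 input) followed by
three conv(3×3)-ReLU-maxpool blocks with 16/32/64 channels and global average
pooling. The stem reflects that the discriminative CTP signal — a
hypoperfused region several millimetres across modulating the enhancement
time course — is regional rather than fine-anatomical; empirically the
coarser working grid also trains more stably at desk scale (fewer noisy
spatial dimensions behind each pooled feature) and keeps a full
forward/backward pass tractable on one CPU. Lower stem factors trade compute
for resolution.

Training details (the reference study does not state its loss, optimizer or
learning rate, so these are package choices): binary cross-entropy, Adam
with learning rate $10^{-3}$, batch size 12, batches drawn without
replacement within a batch, batch-wise standardization to zero mean and unit
variance, then per-sample augmentation (rotation within ±15°, xy-shift
within ±10 px, vertical flip with probability 1/2 — one draw shared by both
slices and all frames of a sample, preserving inter-slice anatomy).
Augmented-in border regions are zero-filled, i.e. filled with the
post-standardization background level.

Two initialization choices matter at desk scale and are deliberate:

* **Zero-initialized fusion head.** Training starts from a calibrated
  p = 0.5 and the first optimizer steps set the direction from data rather
  than from random fan-in noise.
* **Zero-mean temporal filters.** Because one augmentation draw is shared by
  all frames of a sample, every spatial augmentation artifact (borders,
  rotation fill) enters the per-frame feature curves as a *time-constant*,
  per-sample offset, typically an order of magnitude larger than the
  class signal. Temporal filter taps initialized to zero mean along the time
  axis null that static subspace exactly at initialization, so early
  training responds to enhancement dynamics rather than to augmentation
  offsets. This is an initialization, not an architectural constraint — the
  weights are free to move afterwards.

Prediction applies no augmentation and standardizes each prediction batch
with the same batch-wise rule as training (training order — standardize,
then augment — is followed; the reverse order at prediction time is a
no-op since prediction does not augment).

## Cross-validation harness

The cohort is randomly permuted into k = 10 near-equal folds. Iteration *i*
tests on fold *i*, validates on fold *i*+1 (mod k), and trains on the rest,
so every fold serves every role across the k iterations and each sample is
tested exactly once. In the reduced k = 2 desk-scale mode there is no
remaining fold, and the validation fold doubles as the training set — the
documented behavior for the smallest configuration.

Training runs at most `max_epochs` epochs (one epoch = enough random batches
to cover the training role once). After each epoch the validation loss is
computed; training stops once no new minimum has been seen for `patience`
consecutive epochs, and the minimum-validation-loss checkpoint is restored
before the test fold is evaluated. The clinical-scale protocol (500 epochs,
patience 200) is available but desk-scale runs shrink both; the test suite
and the acceptance analysis use 1–15 epochs with n = 12–200 cohorts, sizes
chosen so the full suite completes on a single CPU while still exercising
every code path at the full 128×128×32×2 input geometry.

**Learnability experiments.** The package's standard sanity experiment trains
the tiny-backbone full model on a strongly separated synthetic cohort
(n = 200, `lesion_law_separated()`, noise 0.5 HU) in 2-fold reduced CV and
expects mean test ROC-AUC ≥ 0.9 within fifteen epochs. These runs disable the
augmentation draws (rotation/shift ranges zero, no flips) through the
ordinary `batch_spec()` interface. Augmentation is a regularizer against
overfitting a few hundred clinical samples over hundreds of epochs; in a
ten-epoch learnability check its static per-sample offsets dominate the
gradient signal, so leaving it on would measure regularization noise rather
than whether the architecture, gradients and harness can learn at all. The
batch-generator contract (standardization, draw bounds, shared per-sample
draws) is tested separately with augmentation active.

ROC-AUC uses the rank (Mann-Whitney) formulation with midrank handling of
ties. The mean ROC curve interpolates each fold's staircase onto a common
FPR grid (step 0.01, endpoints pinned at (0,0) and (1,1)) and averages
pointwise. The fold ensemble averages member probabilities arithmetically —
an exact identity tested to machine precision. Ablation arms (full,
global-pathway-only, local-pathway-only) run through the identical
cross-validation path on a shared fold assignment and seed, differing only
in the `pathways` configuration flag.

## Numerical and degenerate-input behavior

* Zero-variance batches are standardized with an epsilon guard and a
  warning.
* All-constant frames register with identity transforms and a warning; an
  all-zero AIF or an empty candidate mask raise errors.
* A degenerate lesion-size law (all volumes identical) warns and labels
  every sample *large* via the tie rule.
* Seeded operations (`simulate_cohort`, `add_noise`, `apply_motion`,
  `make_folds`, `build_model`, `train_fold`) save and restore the caller's
  RNG state; identical seeds give identical outputs. Model training uses
  single-precision convolution kernels, so checkpoints are reproducible on
  one platform but bit-level identity across BLAS builds is not guaranteed;
  predictions from a fixed checkpoint are deterministic.

## Known limitations

* The phantom's two slices share identical anatomy and lesion geometry;
  real ASPECTS-level slices differ.
* CBV estimates from vendor software involve proprietary calibration and
  smoothing; only the threshold rule (CBV < 1.2 mL/100 mL) is reproduced
  here, and absolute agreement with vendor maps is not claimable.
* The clinical headline numbers of the motivating problem (ROC-AUC ≈ 0.7 on
  ~200 patients) depend on a private cohort; the synthetic learnability
  experiments certify that the pipeline can learn a strongly separated
  cohort, which is a much easier task.
* The tiny backbone is a test-mode surrogate: it preserves the architecture
  family (shared-over-time spatial extractor, dual temporal pathways,
  per-slice submodels, sigmoid fusion) at a scale where CPU training is
  feasible, not the representational capacity of a pretrained VGG19.

## A minimal end-to-end run

```{r example, eval = FALSE}
spec <- phantom_spec(noise_sigma = 0.5)
cohort <- simulate_cohort(20, spec, lesion_law_separated(), seed = 1)

# conventional kinetic labeling reproduces the simulator's ground truth
labels <- label_cohort(cohort)
head(labels)

# 2-fold cross-validation of the tiny-backbone classifier
report <- cross_validate(model_config(seed = 1), cohort, k = 2, seed = 1,
                         max_epochs = 10, patience = 10)
print(report)
```
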