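---
title: "Classifying OCT A-scans for serous retinal disease signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying OCT A-scans for serous retinal disease signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascansig)
```

## The problem

In central serous chorioretinopathy (CSCR), serous fluid accumulates in two
strata of the outer retina: between Bruch's membrane (BM) and the retinal
pigment epithelium (RPE), elevating the RPE into a dome — a pigment
epithelial detachment (PED) — and between the neurosensory retina and the
RPE — a serous retinal detachment (RD). Both are visible in volumetric
optical coherence tomography (OCT) scans. The smallest depth-resolved unit
of an OCT volume is the amplitude scan (A-scan): a 1-D reflectivity profile
along the beam axis. This package classifies each A-scan independently as
`PED`, `RD`, or `NEITHER`, and assembles the per-A-scan decisions into en
face probability maps of each signature's spatial distribution.

A volume is indexed `(bscan, ascan, depth)`, depth increasing posteriorly;
the default macular-cube geometry is 256 B-scans x 512 A-scans x 992 depth
pixels over a 6 x 6 mm area (24 such eyes contain 3,145,728 A-scans). A
variant protocol with 902 depth pixels is accepted via the same reader. All
indexing in this package is 1-based, R's native convention.

## The pipeline and its assumptions

1. **Denoising and contrast normalization** (`preprocess_volume()`). Each
   B-scan independently passes through a square median filter (default
   3 x 3, reflection-padded) and contrast-limited adaptive histogram
   equalization (CLAHE; default clip limit 0.01 on the `[0, 1]` scale, 8 x 8
   tiles, 256 bins, computed by EBImage's implementation of Zuiderveld's
   algorithm). The operator sequence — filter, then equalizer — is fixed;
   the parameters are exposed because the method itself does not prescribe
   them, and the defaults are the values commonly used for retinal B-scans.
   CLAHE is deliberately per-B-scan, never volume-wide, so slice-to-slice
   illumination differences are normalized away.

2. **RPE localization** (`locate_rpe()`, `locate_rpe_volume()`). The RPE is
   typically the most reflective band in a retinal A-scan, so its depth is
   estimated as the center of the length-40 depth window with maximal mean
   intensity. We read the "40-pixel neighborhood" as a 1-D window per
   A-scan — the located quantity is a per-A-scan depth, and the 1-D reading
   is the minimal one consistent with that. Conventions are fixed for
   testability: window center is `start + floor((window - 1) / 2)`; tied
   window means resolve to the smallest start (ties are compared with a
   relative tolerance of 1e-9 because the implementation computes window
   sums by cumulative-sum differencing). An optional per-B-scan lateral
   median smoothing of the depth map (width 5, on by default, `0` disables)
   suppresses isolated failures under speckle; it is an additional
   robustness step, not part of the core search.

3. **Feature extraction** (`crop_ascan()`, `build_dataset()`). Each A-scan
   is cropped to 300 px anterior and 100 px posterior of the located RPE,
   inclusive of the RPE pixel — a 401-length reflectivity vector. Positions
   falling outside the profile are zero-padded rather than truncated or
   rejected, so the classifier always sees a fixed-length input. Only
   human-labeled A-scans (`PED`, `RD`, `NEITHER`) enter the dataset;
   `UNLABELED` (equivocal) A-scans are excluded from training and metrics
   but can still be mapped.

4. **Standardization** (`fit_normalizer()`). Features are standardized to
   per-column mean 0 and variance 1 (population variance, floor `1e-8`).
   The normalizer is always fit on the training sample only and applied
   frozen to validation, test, and unseen data; whether the original
   normalization was global or per-split is not specified anywhere, and the
   leakage-free choice is the defensible one. A property test verifies that
   perturbing test-set features cannot change the fitted normalizer.

5. **The classifier** (`init_network()`, `train_mlp()`). A fully-connected
   feed-forward network, 401-200-75-10-3, sigmoid activation on every hidden
   and output layer, three *independent* sigmoid outputs (no softmax),
   binary cross-entropy loss, trained by backpropagation with Adam
   (learning rate 0.001; moment decays 0.9/0.999, epsilon 1e-8, the
   conventional values). The published architecture says input 400 while
   the crop produces 401 features; the two numbers are inconsistent, and we
   size the input layer to the feature length — feature semantics win. The
   remaining training machinery is unstated in the method and fixed here as
   defaults: uniform fan-in-scaled initialization (`U(-a, a)`,
   `a = sqrt(3 / fan_in)`), zero biases, batch size 128, at most 200
   epochs, early stopping after 10 epochs without validation improvement
   with best-validation weights restored, seeded shuffling each epoch.
   Single-label decisions are the argmax of the three sigmoids, ties
   resolving PED > RD > NEITHER (PED is the rarer, clinically distinguishing
   stratum). Class imbalance (RD A-scans outnumber PED by more than 20x in
   CSCR) is handled by balanced subsampling: at most 14,000 samples per
   class, drawn uniformly without replacement.

6. **Evaluation** (`split_dataset()`, `monte_carlo_cv()`,
   `evaluate_unseen()`). The labeled pool is split 80:20 with a validation
   set carved from the training share — 64/16/20, largest-remainder
   rounding, seeded permutation. Monte Carlo cross-validation repeats split,
   balanced sampling, normalizer fitting, training, and scoring over 10
   independently seeded iterations, reporting per-cell mean and SD of the
   row-normalized percentage confusion matrices and of one-vs-rest
   sensitivity/specificity; the SDs are the generalization metric. The
   split is at A-scan level, so A-scans from one eye can occupy both train
   and test; that mirrors the study design but flatters generalization,
   which is why `evaluate_unseen()` exists: it applies a frozen model and
   normalizer to whole eyes never seen in training, enforced by eye id.

7. **Maps** (`probability_map()`, `overlay_boundaries()`,
   `colorize_bscan()`). Probabilities are rendered per class independently
   (PED and RD panels side by side, not argmax-flattened); human-label
   region boundaries (any pixel with a four-neighbor of a different label)
   are overlaid in green (PED) and yellow (RD); B-scans can be tinted per
   A-scan by predicted class. The heat colormap is a perceptually uniform
   ramp (inferno); nothing downstream depends on the specific ramp.

## The synthetic scene generator

No OCT volumes from the underlying study are publicly available, so the
package carries a first-class generator (`scene_config()`, `make_scene()`,
`render_volume()`, `make_cohort()`) that emulates what the pipeline needs to
see, with exact ground truth:

- **Anatomy.** A layered reflectivity profile anchored at the RPE:
  vitreous 0.02, inner retina 0.45, outer nuclear layer 0.12, then a 39-px
  hyperreflective outer complex — the photoreceptor EZ shoulder (0.55), the
  RPE core (0.95, strictly the brightest band), and the
  BM/choriocapillaris shoulder (0.55) — then choroid 0.30. The complex is
  symmetric about the RPE *by design*: the 40-px maximum-mean window then
  provably centers on the RPE core (within the 1-px tie slack) in every
  column type, which is what makes the generator's `rpe_depth_true` a valid
  oracle for the locator. The price is an anatomical simplification: in
  real RD the photoreceptor outer segments detach with the retina, whereas
  here the complex stays with the RPE and the serous cleft separates it
  from the outer nuclear layer. With an asymmetric neighborhood the window
  optimum sits 10-15 px posterior to the RPE in RD columns, and the
  locator and the ground truth could not agree to +/-2 px by any honest
  means.

- **Lesions.** PED and RD are dome-shaped height fields: sums of 2-D
  Gaussian bumps on the en face grid, rounded to whole depth pixels. A PED
  of height `h` elevates the complex `h` px anteriorly off a faint bared BM
  line (0.28) over a serous cavity (0.05) of the full elevation height; an
  RD inserts a cleft (0.05) of its height between retina and complex. A
  column is labeled with a signature when its height exceeds the
  `lesion_threshold` (2 px); PED takes precedence where both exceed it.
  Heights at or below the threshold are treated as sub-resolution: they
  neither render nor label. This keeps the label rule and the rendered
  scene in exact agreement at lesion margins — without it, columns of
  height 2 and 3 px would carry different labels while rendering nearly
  identically, building an irreducible error floor into the benchmark that
  says nothing about the pipeline.

- **Noise and tilt.** Multiplicative gamma speckle with mean 1 (shape 4 by
  default; the relative SD of 0.5 is a standard surrogate for coherent
  speckle — the method itself states no noise model), and a linear axial
  tilt per eye (up to ~0.1 px per lateral px) so absolute depth carries no
  class information.

- **What is deliberately missing.** No attenuation or shadowing, no point
  spread function, no vascular shadow artifacts (a known false-positive
  source on real data), no eye motion, and lesion sizes/heights are
  plausible rather than calibrated against any cohort (none is published).
  Consequently, passing the synthetic benchmark demonstrates that the
  pipeline is implemented correctly and can recover a known signal under
  speckle — not that the reported clinical accuracies would be reproduced
  on patient data.

## Study conditions and problem sizes

The package's standard synthetic conditions (`benchmark_scene_config()`,
`synthetic_benchmark()`) are a 12-eye cohort at 64 B-scans x 128 A-scans x
512 depth px with the RPE resting at depth 280, per-eye randomized lesions
(1-3 PED domes with 8-28 px peaks, 1-2 broader RD blisters with 10-40 px
peaks), gamma-4 speckle, and 10-iteration Monte Carlo cross-validation with
a per-class quota of 2000 and at most 120 epochs. These sizes are the
package's chosen desk-scale conditions: small enough to run a full
cross-validation in minutes on one core, large enough that every class has
thousands of labeled A-scans. Whole-eye generalization
(`unseen_generalization()`) trains on 6 eyes and scores 3 disjoint unseen
eyes. All randomness flows from one master seed through a deterministic
seed-derivation stream, so every figure the package reports is exactly
reproducible.

## Numerical choices and degenerate inputs

- Window-mean ties in the RPE search resolve to the smallest start, with a
  relative tolerance of 1e-9 absorbing cumulative-sum round-off.
- Predictions are clipped to `[1e-7, 1 - 1e-7]` before the cross-entropy
  logarithms; gradients ignore the clip (standard practice).
- Constant feature columns have zero variance and standardize to 0 via the
  variance floor; standardization is exactly invertible on non-constant
  columns.
- Confusion rows with no actual samples are reported as zero rows and
  flagged, not silently normalized; zero denominators in
  sensitivity/specificity yield `NA`, never errors.
- CLAHE on a constant image returns it unchanged; images whose sides are
  not tile-grid multiples are edge-padded for the transform and cropped
  back.
- Integer-typed volumes rescale by the dtype maximum on read; float inputs
  outside `[0, 1]` are clipped with a warning. TIFF stores 32-bit float
  pages (exact at single precision); the raw-binary format with a JSON
  sidecar round-trips float64 bitwise.

## Known limitations

The synthetic benchmark is a correctness and recovery test, not a clinical
validation; the generator's omissions listed above bound what it can show.
The A-scan-level split shares eyes between train and test by construction —
use the whole-eye evaluation for honest generalization numbers. The
classifier is deliberately the small printed architecture; no convolutional
context, no hyperparameter search, and no GPU path are provided.

## A worked example

```{r example, eval = FALSE}
library(ascansig)

# a small synthetic cohort with ground-truth labels
cohort <- make_cohort(4, benchmark_scene_config(seed = 3), seed = 3)
fs <- build_dataset(lapply(cohort, `[[`, "volume"),
                    lapply(cohort, `[[`, "label_map"))

# cross-validated performance
st <- benchmark_settings(seed = 3)
report <- monte_carlo_cv(fs, split_spec(seed = 11), st$network, st$budget,
                         n_iterations = 2)
cv_class_accuracy(report)

# en face probability maps for one eye
fitted <- train_cohort_model(cohort, seed = 3)
pm <- probability_map(fitted$model, fitted$norm, cohort[[1]]$volume)
img <- overlay_boundaries(pm, cohort[[1]]$label_map, class = "PED")
write_image_png(img, "ped_map.png")
```
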