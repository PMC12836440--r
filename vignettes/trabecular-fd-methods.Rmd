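---
title: "Box-counting fractal analysis of condylar trabecular bone: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box-counting fractal analysis of condylar trabecular bone: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condylefd)
```

## The measurement problem

Degenerative change in the temporomandibular joint remodels the spongy
(trabecular) bone of the mandibular condyle before it produces obvious
outline changes on a radiograph. The box-counting fractal dimension (FD)
summarizes how completely a binary trabecular pattern fills the plane: a
denser, more complex lattice has a higher FD, and condylar bone in
temporomandibular disorder (TMD) tends to score lower than in healthy
joints. `condylefd` implements the full measurement chain for panoramic
radiographs — ROI extraction, a ten-step texture-to-skeleton
preprocessing pipeline, box counting with log–log regression — together
with the cohort statistics and the six-classifier benchmark used to judge
FD's diagnostic value.

## The preprocessing pipeline

`preprocess_roi()` executes ten steps in fixed order, each retained in
the returned trace so the standard montage can be inspected or exported
with `save_trace_steps()`:

1. **ROI** — a 100 × 100 px window at operator-supplied `(x, y)`
   (0-based, top-left origin, half-open). The window size gives adequate
   subchondral coverage while avoiding superimposed anatomy.
2. **Duplicate** — the working copy.
3. **Gaussian blur** (`gaussian_sigma`, default 35 px) — estimates the
   slowly varying background: soft-tissue shadow, ramus density gradient.
4. **Subtraction** of the blurred image from the duplicate — leaves the
   local trabecular texture, clamped at 0.
5. **Addition of 128** gray levels — recenters the texture mid-scale so
   both above- and below-background structure is representable.
6. **Binarization** at gray level 128, strict `>` — after recentering,
   foreground is exactly the above-background texture.
7. **Erosion** and 8. **dilation** (3 × 3 square element, 1 iteration
   each) — a morphological opening that removes speckle noise.
9. **Inversion** — swaps foreground and background, mirroring the binary
   display convention of the macro environment this protocol originated
   in.
10. **Skeletonization** — parallel Zhang–Suen thinning to a 1-px network
    whose space-filling behavior the box counter measures.

All arithmetic is 8-bit saturating; blur borders use edge replication;
morphology treats out-of-image pixels as background (erosion) with the
mirrored convention available for duality checks. Every choice is a
configurable `pipeline_config()` field and is echoed into each output
record, because FD values are only comparable under identical settings.

Parameters the protocol leaves open were fixed as follows and exposed in
the configuration rather than hard-coded: the blur sigma (35 px, the
established value for dental-radiograph fractal work at this ROI size —
large enough to model background, small enough to keep trabecular
detail), the binarization threshold (128, the natural cut after
recentering), and the structuring element (3 × 3 square, one pass, the
common default of macro-driven morphology).

Degenerate inputs are a first-class outcome, not a number: if
binarization finds no foreground (a flat or featureless ROI), the
skeleton is defined as empty — there is no texture whose medial axis
could be meant — and `fd_from_image()` raises a "degenerate ROI" error
instead of reporting an FD.

A note on thinning: the parallel Zhang–Suen scheme guarantees the
skeleton is a subset of its input, is idempotent, and preserves
8-connectivity, but it can retain isolated 2 × 2 pixel artifacts at
complex junctions. This is a documented property of the algorithm family,
immaterial to box counts at the scales used.

## Box counting

`count_boxes()` overlays a single top-left-anchored grid of edge ε and
counts occupied cells, partial edge boxes included; offset averaging is
deliberately absent, mirroring the automated macro protocol.
`fractal_dimension()` fits ordinary least squares of log N(ε) on log ε
and reports FD = −slope with the fit's R². The default edge schedule
{2, 3, 4, 6, 8, 12, 16, 32, 64}, capped at the shorter image side, is the
macro environment's standard set; because the schedule affects
cross-study comparability it is echoed in every record. A post-fit
assertion enforces FD ∈ (0, 2]: patterns too sparse to scale (a single
pixel, a handful of isolated dots) raise a diagnostic rather than
returning a meaningless slope.

Validity is anchored on closed-form fixtures: the depth-5 Sierpiński
carpet (FD = log 8 / log 3 ≈ 1.8928, recovered exactly on the aligned
schedule {1, 3, 9, 27, 81}), a 1-px line (FD ≈ 1) and a filled square
(FD ≈ 2):

```{r fixtures}
fractal_dimension(make_sierpinski_carpet(5), c(1L, 3L, 9L, 27L, 81L))$fd
fractal_dimension(make_line(243))$fd
fractal_dimension(make_filled_rect(243, 243))$fd
```

## What the synthetic data emulates — and what it does not

No radiographs or subject-level data accompany the study this package
operationalizes, so the `synthetic` layer generates every fixture in
code.

**Textures.** `make_trabecular_texture()` synthesizes power-law
(1/f^β) random fields, rescaled to 8 bits. The complexity dial maps
linearly onto the spectral exponent, β = 3.5 − 2·complexity, spanning
the fractional-Brownian regime β ∈ [1.5, 3.5]. Higher complexity means
more high-spatial-frequency energy — the statistical signature of a
finer, denser trabecular lattice — and the end-to-end pipeline FD rises
monotonically with it. The lower β bound stays at 1.5 by design:
below it the field approaches white noise, whose binarization fills
boxes at every scale and saturates the estimator, destroying the
dial's meaning. These fields reproduce the *scaling* behavior of
trabecular texture, not its anatomy: no condylar outline, no cortical
rim, no superimposed airway shadows, no osteophytes or Ely's cysts. A
passing pipeline suite therefore demonstrates correct measurement of
scaling structure, not clinical performance on radiographs.

**Cohorts.** `simulate_cohort()` draws (LC_FD, RC_FD) per subject from a
bivariate normal per (group, age band, gender) cell, truncated to (0, 2],
with cell sizes, means and SDs taken literally from the published
descriptive tables (`condyle_fd_reference_cells()`): 220 subjects, 110
TMD patients and 110 age-matched controls across bands 18–29, 30–39,
40–49 and ≥50 (capped at 75, the study's upper age). A normal model is
justified by the published normality screen, in which every cell but one
passed Shapiro–Wilk. Two quantities the study does not report had to be
chosen: the within-subject left–right correlation (ρ = 0.5 by default,
configurable — a moderate positive dependence is the physiological
expectation for paired condyles; tests never depend on its exact value)
and ages within a band (uniform). The published control table prints
inconsistent gender counts between its left- and right-condyle blocks;
the left-condyle composition (whose totals match the study design) is
used for both.

## Statistical layer

- `descriptive_stats()`: n / mean / sample SD (n−1) per cell; single-
  subject cells keep their mean with an `NA` SD, empty cells are kept
  with n = 0.
- `compare_groups()` gates on Shapiro–Wilk (α = 0.05) in **both** arms:
  jointly normal data get the equal-variance two-sided t-test, anything
  else the two-sided Mann–Whitney U. Equal-variance Student's t was
  chosen over Welch because the accompanying effect size pools the SDs —
  the printed effect sizes are reproduced exactly under this pairing —
  and a Welch option would be an API addition, not a correction.
- `cohens_d()` uses the pooled-SD definition with the patient moments
  first, so negative d means lower FD in patients.
- `bonferroni()` multiplies by the comparison count and caps at 1. The
  combined-condyle table corrects across its fixed 8 strata and labels
  tiers (Significant < 0.05, Highly Significant < 0.005 on the corrected
  p) — a presentation rule reverse-engineered from the published table's
  labels, not an inferential claim. The published corrected values are
  not a constant multiple of the printed raw p-values (0.0008 → 0.0096
  is ×12, not ×8); the package documents and applies its own arithmetic,
  p·8 capped at 1.
- `icc_2_1()` implements the two-way random-effects, absolute-agreement,
  single-measure intraclass correlation from the classical mean-squares
  decomposition with the Satterthwaite-approximated F interval. It
  reproduces the classic published worked example (0.29) and matches an
  independent implementation to 6 decimals on a frozen fixture.

Calibration is tested, not assumed: under the null (both arms from one
normal distribution, n = 26 per arm, 2000 replicates) the gated
comparison rejects at 5% ± 1.5%.

## Classifier benchmark

`build_features()` encodes {age, gender (male = 0 / female = 1), LC_FD,
RC_FD}, labels patients 1, splits 70/15/15 stratified by label
(largest-remainder rounding reconciled to the whole-sample split: 220 →
154/33/33), and z-scores with moments fitted on the training partition
only — the same fitted scaler transforms validation and test, so no
information leaks. One row per subject is the default granularity; the
originating study's feature-count bookkeeping (621 = 433 + 94 + 94)
cannot be reconciled with 220 subjects × 4 features and is not imitated.

Six families run at their R implementations' documented defaults:
random forest (500 trees), logistic regression (IRLS), RBF-kernel SVM
(C = 1, decision values as scores), gradient boosting (depth-3 trees,
learning rate 0.1, 100 rounds), 5-nearest-neighbors (vote fractions as
scores), and XGBoost (library defaults, 100 rounds). Both boosted
families use the exact greedy split finder rather than histogram
binning: with the small tabular feature set there is no speed argument
for binning, and exact splits fall at gap midpoints, which generalizes
correctly on widely separated clusters. Every stochastic fit is seeded;
`cross_validate()` uses stratified folds (220 rows → 5 folds of 44) and
reports mean ± SD of accuracy, precision, recall, F1 and trapezoidal
ROC-AUC; models are ranked by mean accuracy with AUC as tie-break. The
holdout report evaluates each family on the validation and test
partitions and prints the test confusion matrix under both
patient-positive and control-positive conventions, because published
summary metrics for such benchmarks are consistent only under the
latter. Feature importances (split gain, normalized to sum 1) are
available for the tree ensembles only; other families raise an explicit
unsupported-model error.

Because the cohorts here are synthetic, the benchmark's absolute
performance is a property of the simulation, not of the study's
radiographs: at the published cell moments the cross-validated AUC of
the boosted model is approximately 0.70 — clearly above chance by more
than three fold-standard-errors, but far below the ~0.95 reported on the
real single-center data. The tests therefore assert signal detection and
null calibration (accuracy 0.5 ± 0.1 on zero-separation cohorts), never
the published point values.

## Numerical choices and degenerate inputs

- Blur kernels truncate at 3σ and normalize; separable passes with
  per-axis index clamping are exactly equivalent to full 2-D
  convolution with edge replication, which the brute-force oracle test
  exploits.
- Saturating integer arithmetic throughout the grayscale chain; images
  are validated to integer [0, 255] at every boundary.
- OLS on (log ε, log N) in natural logs; the base cancels in the slope.
- Ties in KNN voting cannot occur for binary labels with k = 5; SVM
  class predictions come from the sign of the decision value.
- Zero-variance samples: Shapiro–Wilk refuses them explicitly; Cohen's d
  refuses a zero pooled SD; `metrics_from_confusion()` reports
  undefined metrics as `NA`, never silently 0.
- All generators save and restore the caller's RNG state, so they are
  pure functions of (parameters, seed).

## Problem sizes used by the test suite

The suites exercise the smallest sizes at which each property is
meaningful: 50 × 50 images for box-count oracle equivalence (100
replicates), 24 × 24 for morphology oracles, 32 × 32 for the blur
oracle, 128 px textures with 20 seeds per complexity level for the
monotonicity experiment, 2000 replicates for type-I calibration, and the
full 220-subject default cohort for the ML layer. The complete suite
runs in well under a minute on a single core.

## Known limitations

- ROI placement is operator input; no condyle localization is attempted.
- Physical pixel spacing is not modeled; FD here is a function of the
  pixel raster, and values are comparable only at equal resolution and
  equal box-size schedules.
- Single-grid box counting (no offset averaging) matches the automated
  macro protocol but adds small anchor-dependent variance; an
  offset-averaging variant would change absolute values and is out of
  scope.
- The synthetic cohort reproduces first and second moments per cell, not
  the full joint distribution of real populations; classifier rankings
  on it need not transfer to clinical data.
- DICOM input is not supported; PNG/TIFF (8- or 16-bit, converted to
  8-bit) are the accepted formats.
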