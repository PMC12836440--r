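# condylefd

Automated box-counting fractal analysis of condylar trabecular bone on
panoramic dental radiographs, with the cohort statistics and machine-learning
benchmark used to evaluate fractal dimension (FD) as a marker of
temporomandibular disorder (TMD).

Trabecular bone remodeling in the temporomandibular joint changes the
space-filling complexity of the condyle's radiographic texture. The
box-counting fractal dimension quantifies that complexity: cover the
binarized, skeletonized texture with grids of edge ε, count occupied cells
N(ε), and fit

    log N(ε) = −FD · log ε + c

by ordinary least squares; FD = −slope, with FD ∈ (0, 2] for a planar
pattern. Lower FD indicates a sparser, less complex trabecular lattice, as
seen in degenerative joint disease.

The package provides, in one coherent chain:

- **Image I/O** — PNG/TIFF radiograph loading normalized to 8-bit grayscale,
  ROI extraction with an explicit 0-based, half-open raster convention.
- **Ten-step preprocessing** — duplicate, Gaussian background blur
  (σ = 35 px), subtraction, +128 recentering, binarization, morphological
  opening (erode + dilate, 3 × 3), inversion, Zhang–Suen skeletonization;
  every intermediate retained and exportable as the standard montage.
- **Box counting** — single top-left-anchored grid per scale, edge schedule
  {2, 3, 4, 6, 8, 12, 16, 32, 64}, OLS on the log–log curve with R².
- **Synthetic fixtures** — Sierpiński carpets, lines and filled squares with
  closed-form dimensions; power-law textures with a monotone complexity
  dial; simulated 220-subject cohorts parameterized by the published
  per-cell FD means and SDs of TMD patients and age-matched controls.
- **Cohort statistics** — descriptives, Shapiro–Wilk-gated t/Mann–Whitney
  comparisons, pooled-SD Cohen's d, Bonferroni correction with significance
  tiers, ICC(2,1) observer agreement with 95% CI.
- **Classifier benchmark** — standardized features {age, gender, LC_FD,
  RC_FD}, stratified 70/15/15 split (seed 42), six families (random forest,
  logistic regression, SVM, gradient boosting, KNN, XGBoost), stratified
  5-fold CV metrics, ROC/PR curves, confusion matrices under both
  positive-class conventions, split-gain feature importance.

## Worked example

Measure the FD of a trabecular texture:

```r
library(condylefd)

tex <- make_trabecular_texture(128, complexity = 0.7, seed = 3)
res <- fd_from_image(tex, roi_spec(14, 14), subject = "demo", side = "left")
res$result
#> Box-counting fractal dimension: 1.4881 (R^2 = 0.9871)
#>   box sizes: 2 3 4 6 8 12 16 32 64
#>   counts:    704 467 346 217 146 77 47 16 4
```

The counts fall roughly as ε^−1.49 across scales (R² = 0.99), i.e. the
skeletonized texture fills the plane more completely than a curve (FD 1) and
less than a disk (FD 2) — the regime in which trabecular bone lives.

Simulate a cohort at the published group moments and run the statistics and
the benchmark:

```r
cohort <- simulate_cohort(seed = 42)        # 110 TMD patients + 110 controls
cmp <- comparison_table(cohort)
cmp[cmp$age_group == "40-49", c("condyle", "test_name", "p_value", "cohens_d")]
#>   condyle          test_name  p_value cohens_d
#> 4   LC_FD independent t-test 1.27e-04    -1.15
#> 8   RC_FD independent t-test 9.21e-09    -1.91

f <- build_features(cohort, seed = 42)      # 154/33/33 stratified split
benchmark_classifiers(f, k = 5, seed = 42)
#> Six-classifier benchmark (5-fold CV, seed 42)
#>   1. Support Vector Machine acc 0.69+/-0.08  F1 0.68+/-0.10  AUC 0.70+/-0.09
#>   2. Logistic Regression    acc 0.68+/-0.07  F1 0.67+/-0.09  AUC 0.71+/-0.07
#>   3. Random Forest          acc 0.67+/-0.04  F1 0.67+/-0.04  AUC 0.71+/-0.08
#>   4. K-Nearest Neighbors    acc 0.66+/-0.05  F1 0.65+/-0.06  AUC 0.68+/-0.06
#>   5. XGBoost                acc 0.65+/-0.05  F1 0.66+/-0.06  AUC 0.70+/-0.05
#>   6. Gradient Boosting      acc 0.63+/-0.07  F1 0.64+/-0.08  AUC 0.72+/-0.07
```

Negative Cohen's d means lower FD in patients. On this synthetic cohort the
classifiers separate the groups well above chance (AUC ≈ 0.7); absolute
performance on real radiographs is a property of real data and is not
reproduced by simulation.

## Command line

An installed `condylefd` script wires the same functions:

```sh
condylefd simulate --defaults --seed 42 --out cohort.csv
condylefd stats    --cohort cohort.csv --out stats_out/
condylefd train    --cohort cohort.csv --seed 42 --cv 5 --out train_out/
condylefd fd       --image roi.png --roi 14,14 --save-steps steps/ --out fd.csv
```

Each output directory receives a `manifest.json` with the resolved
parameters, seed, input digests and package version.

## Package layout

```
R/                  implementation (image I/O, pipeline, box counting,
                    synthetic data, cohort statistics, classification, CLI)
exec/condylefd      command-line entry point
tests/testthat/     unit, property and end-to-end suites with
                    brute-force oracles
scripts/acceptance.R   headline-quantity reproduction script
vignettes/          methods vignette: model, parameters, design decisions
```
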