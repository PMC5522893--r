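---
title: "Statistical shape modelling of landmark cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modelling of landmark cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(shapemodes)
library(dplyr)
```

## The problem

Joint morphology — the outline of a proximal femur on a hip DXA scan, or of
the vertebral bodies on a lateral spine scan — is hard to summarise with a few
geometric measurements, and hand-picked measures (neck-shaft angle, lordosis
angle) are highly inter-correlated. Statistical shape modelling (SSM) instead
places a fixed template of landmark points on each image (here 68 points for
the hip, 89 for the spine), removes location, orientation and global size by
Procrustes superimposition, and summarises the remaining *shape* variation by
principal components. Each subject is then described by a handful of mode
scores in standard-deviation units — 0 on every mode is the cohort mean shape —
and those scores feed ordinary cohort statistics: sex comparisons, correlations
with anthropometry and bone mineral density, and cross-joint correlations.

This package implements that pipeline end to end, together with a
ground-truth synthetic cohort generator so that every stage can be validated
without access to any restricted imaging data.

## Alignment: generalized Procrustes analysis

`center_and_scale()` maps each configuration to its *preshape*: centroid at
the origin, centroid size (the square root of the summed squared distances of
points to their centroid) scaled to 1. Size is removed entirely — full
Procrustes — because global size is a nuisance variable in this design, not a
variable of interest.

`gpa()` then iterates the classical scheme: initialise the consensus as the
first preshape; rotate every preshape onto the consensus (`optimal_rotation()`
solves this in closed form; in 2D the optimal angle is the argument of the
complex inner product of the two point vectors); recompute the consensus as
the renormalised mean of the rotated shapes; stop when the Procrustes distance
between successive consensuses falls below `tol`.

Numerical and design choices:

* **Reflections are never allowed** in the rotation solve. Inputs are assumed
  consistently oriented (in practice, one side's images are mirrored before
  marking); a reflected configuration is a different shape and shows up as a
  large residual rather than being silently folded.
* **Rotation gauge.** The converged consensus has an arbitrary overall
  rotation. It is fixed deterministically by rotating the whole set so the
  consensus is optimally aligned with the first subject's preshape. This makes
  repeated runs byte-identical; tests that compare a fitted model against a
  generator's ground truth first undo this gauge (`align_to_truth()`).
* **No per-iteration rescaling** of individual shapes after the initial
  unit-size projection: the iteration acts on preshapes only, the simplest
  scheme consistent with "scale, rotate and translate".
* Defaults `tol = 1e-8`, `max_iter = 100`. On cohorts of up to 2000 noisy
  synthetic shapes the iteration converges in well under ten iterations.
* Residuals are computed by direct differencing of the rotated coordinates
  rather than via `sqrt(2 - 2|inner|)`, which loses half the significant
  digits near zero.

Whether the original study iterated to a consensus or aligned to a fixed
reference is not stated in the one-line description such papers give;
GPA-to-consensus is the standard construction for shape models and is what is
implemented.

## The point-distribution model

`fit_shape_model()` performs PCA on the aligned coordinates. One deliberate
refinement: each aligned unit-size shape is first mapped to **Kendall tangent
coordinates**, rescaling it by the inverse of its dot product with the
consensus. This is the classical Cootes-style construction, and it is what
makes the scoring contract exact rather than approximate:

* the residuals are exactly orthogonal to the consensus and to its
  infinitesimal rotation, so the similarity directions carry exactly zero
  variance;
* scoring the model mean returns exactly 0 on every mode, under any similarity
  transform of the mean;
* rescoring the training sample returns mean 0 and SD 1 per mode exactly
  (denominator `n - 1` throughout, so `raw_sd^2` equals the eigenvalue
  exactly);
* `score(reconstruct(mode k, +2))` returns exactly 2 on mode k and 0
  elsewhere.

Without the tangent rescaling all of these hold only to the order of the
cohort's shape variance (about 1e-2 here), not to numerical precision.

PCA is on the **covariance**, not the correlation: all coordinates share
units, and per-coordinate standardisation would inflate the quietest
landmarks. Eigenvector signs are fixed by a deterministic convention (the
largest-magnitude coefficient is made positive; ties break to the lowest
coordinate index), so fitted models are reproducible; comparisons against any
external table of scores remain direction-agnostic because the sign of a
principal axis is not identifiable.

Out-of-sample configurations are scored by aligning to the model consensus
only — the cohort alignment is not re-run — so scores are stable as new
subjects arrive. Mode counts default to 10 (hip) and 8 (spine), matching the
usual practice of cutting the scree where modes drop below about 2% of
variance; `select_modes()` also offers fixed counts and cumulative-variance
targets. Normalisation always uses the fitting sample's SDs.

Degenerate inputs fail loudly: coincident points, an all-identical cohort
(zero total variance), or a requested mode count beyond the numerical rank
(eigenvalues above `1e-12` times the largest).

## Cohort statistics

The statistics layer mirrors how such cohort tables are built and read:

* `ttest_raw()` / `ttest_summary()`: two-sided **pooled-variance Student's
  t** (the classical "Student's t-test"), with the summary form reproducing
  the identical statistic from printed "mean (SD)" rows — that is what makes
  published tables re-testable. Welch's correction is deliberately not used;
  at these group sizes and SD ratios the difference is immaterial.
* `partial_correlation()`: both variables are residualised by least squares on
  an intercept plus dummy-coded scanning centre (CRF, 6 levels; reference =
  first level lexicographically) and the Pearson correlation of residuals is
  returned. No small-sample degrees-of-freedom correction is applied to r — in
  cohorts of ~1500 the correction is invisible, and the convention in this
  literature is to interpret |r| against a 0.1 threshold rather than p-values.
* The **flag rule** marks |r| ≥ 0.1 by default (printed tables bold
  "magnitudes 0.1 or greater"); a strict `>` rule is available.
* `adjusted_sex_association()` answers "does the sex difference survive
  adjustment for height?" by OLS of score on sex + covariates. The exact form
  of such adjustments is often unstated in papers; OLS with a sex indicator is
  implemented and labelled as such, and with no covariates it reproduces the
  pooled t-test exactly.
* No multiple-testing correction is applied anywhere, matching the
  interpretation-by-threshold convention; outputs carry the threshold used.
* All analyses are sex-stratified by default.

## Repeatability

`point_error()` quantifies marking repeatability as the Euclidean distance in
raw pixels between corresponding points of two markings — deliberately
**without** Procrustes alignment, because the quantity of interest is the
digitisation error on the image, in image units. "Difference between
coordinates" is ambiguous between Euclidean distance and per-axis differences;
the Euclidean distance is the primary statistic and per-axis mean absolute
differences are emitted alongside. Similarly, pooling all distances versus
averaging per point/per subject is ambiguous; the pooled mean is primary and
both per-point and per-subject means are returned.

## The synthetic generator

`make_true_model()` + `generate_cohort()` define the study conditions for all
recovery tests. The generator emulates:

* a low-rank mode structure: smooth random displacement fields (Gaussian
  kernel over point index within each outline group, width 3 — anatomical
  modes are spatially smooth), orthonormalised against each other **and**
  against the similarity directions, so injected variance lives entirely in
  shape space;
* a variance spectrum given as fractions of a total Procrustes variance;
* per-mode sex offsets in SD units, applied to males;
* covariates (height, weight, hip/spine BMD; BMI derived as
  weight/height², as such studies compute it) with per-sex means and SDs on
  realistic scales (men 1.75 (0.06) m, 85.2 (12.8) kg; women 1.62 (0.06) m,
  71.5 (12.4) kg), small scanner-calibration offsets per centre on BMD, and
  **calibrated loadings**: a loading of ρ on mode k makes the within-sex
  population correlation between the covariate and that mode's score exactly
  ρ, which is what the partial-correlation recovery tests measure;
* per-subject nuisance similarity transforms (±10° rotation, ±0.1 log-scale,
  ±20 px translation around the nominal image centre) and i.i.d. Gaussian
  digitisation noise in pixels.

Two calibration decisions matter for interpretation:

1. **The noise is part of the leftover variance budget.** The fraction of
   variance not assigned to the true modes is an isotropic floor; the pixel
   noise, mapped into preshape units at the nominal centroid size, is counted
   inside that floor (the explicit residual field carries the remainder).
   Measured eigenvalues are then `f_k * T + floor` on mode directions and
   `floor` elsewhere, so the empirical scree matches the injected fractions
   to within the floor spacing (~0.15 percentage points here) plus sampling
   error, rather than being shifted by the noise. A noise level exceeding the
   leftover budget is rejected as infeasible.
2. **Default scenarios.** The hip scenario uses 68 points, 10 modes with
   fractions (23.0, 17.0, 12.8, 6.9, 5.2, 4.1, 3.5, 3.2, 2.8, 2.1)% — mode 1
   23%, first three 52.8%, first ten 80.6% — total Procrustes variance 0.015,
   nominal centroid size 700 px on a 300×252 image, noise 2.6 px (the
   inter-rater marking error scale). The spine scenario uses 89 points, 8
   modes with fractions (53.0, 12.0, 6.5, 4.0, 3.2, 2.7, 2.3, 1.2)% — first
   eight 84.9% — total variance 0.02, centroid size 2500 px on a 400×1200
   image, noise 2.2 px. Sex offsets echo the per-mode differences reported
   for hips and spines (the largest, ~1 SD, on spine mode 3), and the hip
   weight loading of 0.19 on mode 2 matches the strongest reported
   mode-covariate correlation. The totals (0.015/0.02) are chosen once as
   plausible Procrustes variances for bone outlines and large enough that the
   documented noise fits inside the leftover budget; they are not fitted to
   anything.

What the generator does **not** emulate: correlated (anatomically structured)
digitisation error, non-Gaussian score distributions, outliers and
poor-quality scans, missing landmarks, or any image content at all. Passing
recovery tests therefore demonstrates the estimator chain is correct under
the stated statistical model, not that real DXA cohorts satisfy that model.

## What the tests pin down

```{r recovery, eval = FALSE}
truth <- default_hip_truth()
cohort <- generate_cohort(truth, n = 1633, seed = 1)
model <- fit_shape_model(gpa(cohort$landmarks), n_retained = 10)
tidy(model)[1:10, ]
```

At the study scale used throughout (hip n = 1633, spine n = 1529, joint set
1511, three seeds in the heavier tests), the suite verifies: per-mode variance
percentages within ±1.5 points of the injected fractions; the leading 3-mode
subspace within 10° of the truth (after undoing the rotation gauge); every
injected sex-offset direction recovered by the downstream t-tests; the
injected weight-mode partial correlation of 0.19 recovered within ±0.05;
t-test p-values uniform under the null (Kolmogorov-Smirnov over 200
replicates); cross-joint correlations of independently generated joints inside
the 3/√n sampling band in ≥95% of cells; and marking noise reproducing the
Rayleigh closed form (mean error σ√π when both markings carry per-axis noise
σ) within Monte-Carlo error. Smaller oracle tests check the rotation solve
against a grid search, the PCA against an explicitly assembled covariance
eigendecomposition, and the partial correlation against normal-equations
residuals.

Two honest caveats surfaced by the recovery tests. The Procrustes consensus
carries a curvature bias of order the total shape variance relative to the
generator's arithmetic mean, so mean-shape recovery is asserted at that scale
(0.05) in the noisy hip scenario and at 0.01 in a low-variance scenario.
And when eigenvalues are closely spaced, neighbouring estimated modes mix;
a mode with no injected sex offset can then show a small spurious sex
difference borrowed from its neighbours. That is a property of PCA itself,
worth remembering when interpreting higher modes of real cohorts.

## Known limitations

2D landmarks only; no sliding semi-landmarks, no missing-landmark estimation,
no 3D alignment, no automatic landmark search on images, and no probabilistic
or robust PCA variants. The shipped hip/spine templates are plausible
hand-constructed outlines for simulation and plotting — they are not a
clinical marking protocol.
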