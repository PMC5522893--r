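# shapemodes

Statistical shape modelling (SSM) of 2D landmark cohorts, for studies of
skeletal morphology — for example the shapes of the proximal femur and the
lumbar spine marked on DXA images across a large birth cohort — and for anyone
who needs a tested, reproducible landmark → Procrustes → PCA → cohort-statistics
pipeline with a ground-truth simulator attached.

## What it computes

Given one landmark configuration per subject (a fixed template of *k* points,
pixel coordinates), the pipeline:

1. **Aligns** the cohort by generalized Procrustes analysis: each
   configuration is centred, scaled to unit centroid size
   (`S = sqrt(Σᵢ ‖xᵢ − x̄‖²)`), and iteratively rotated onto a consensus mean
   shape until the consensus stabilises. Reflections are never used.
2. **Fits a point-distribution model**: PCA of the aligned coordinates in
   Kendall tangent space. Mode *j* is an orthonormal eigenvector **v**ⱼ of the
   sample covariance with eigenvalue λⱼ; a subject's normalised score is

   `score_j = vⱼᵀ (x_aligned − x̄) / sqrt(λⱼ)`

   so scores are in SD units with 0 = the cohort mean shape, and a shape can
   be reconstructed at ±c SD along mode j as `x̄ ± c·sqrt(λⱼ)·vⱼ`.
3. **Selects modes** from the scree (fixed count, per-mode % threshold, or
   cumulative-% target) and reconstructs ±2 SD mode shapes for visualisation.
4. **Runs the cohort statistics** used in this literature: pooled Student's
   t-tests of sex differences per mode (also computable from printed
   "mean (SD)" table rows), Pearson and centre-adjusted partial correlations
   of scores with height, weight, BMI and BMD with an |r| ≥ 0.1 reporting
   flag, covariate-adjusted sex associations, and cross-joint mode-by-mode
   correlation tables.
5. **Quantifies marking repeatability** as the mean pixel distance between
   corresponding points of repeated markings.
6. **Simulates cohorts with known ground truth** — low-rank smooth modes, a
   chosen variance spectrum, sex offsets, calibrated covariate loadings,
   nuisance similarity transforms and digitisation noise — so every stage
   above is testable end to end (`default_hip_truth()` is a 68-point,
   10-mode, n≈1600-scale scenario; `default_spine_truth()` an 89-point,
   8-mode one).

Everything takes and returns tidy tibbles; fitted objects have `tidy()`,
`glance()`, `autoplot()` (scree, aligned cloud) and `plot_mode_variation()`
methods. `run_study()` orchestrates the full two-joint study from three input
files to a directory of CSV/JSON outputs with an accounting log.

## Worked example

```r
library(shapemodes)
library(dplyr)

truth  <- default_hip_truth()                      # known ground truth
cohort <- generate_cohort(truth, n = 400, seed = 11)

aligned <- gpa(cohort$landmarks)
glance(aligned)
#>   n_shapes n_points n_iterations converged mean_residual max_residual
#> 1      400       68            4 TRUE              0.121        0.205

model <- fit_shape_model(aligned, n_retained = 10)
model
#> <shape_model 'hip': 68 points, fitted on 400 shapes, 10/132 modes retained>
#>   retained modes explain 81.8% of variance (mode 1: 23.6%)

head(tidy(model), 4)
#>    mode pct_variance cumulative_pct variance raw_sd retained
#> 1     1        23.6            23.6  0.00368 0.0607 TRUE
#> 2     2        17.4            41.0  0.00272 0.0522 TRUE
#> 3     3        13.7            54.7  0.00215 0.0463 TRUE
#> 4     4         7.15           61.9  0.00112 0.0334 TRUE

scores <- score_shapes(model, cohort$landmarks)
head(sex_difference_table(scores, cohort$records), 3)
#>    mode  n_m mean_m  sd_m   n_f mean_f  sd_f mean_difference     t    df
#> 1     1  180  0.180 0.986   220 -0.147 0.989           0.327  3.29   398
#> 2     2  180  0.295 0.928   220 -0.241 0.994           0.536  5.53   398
#> 3     3  180 -0.175 0.939   220  0.143 1.03           -0.318 -3.20   398

correlation_table(scores, cohort$records, c("weight_kg", "bmi")) |>
  filter(mode == 2)
#>   sex    mode variable       r n_used adjusted_for flagged
#> 1 F         2 weight_kg 0.127     220 crf          TRUE
#> 2 F         2 bmi       0.0918    220 crf          FALSE
#> 3 M         2 weight_kg 0.239     180 crf          TRUE
#> 4 M         2 bmi       0.248     180 crf          TRUE
```

Reading the output: the alignment converged in 4 iterations with a mean
Procrustes residual of 0.12 (the cohort's shape spread in preshape units);
mode 1 carries 23.6% of shape variance and the ten retained modes 81.8%, close
to this scenario's injected spectrum (23%, 80.6%); the generator's male-ward
offsets on modes 1 and 2 and female-ward offset on mode 3 come back with the
right directions and p-values; and the injected weight loading on mode 2
(population r = 0.19) is estimated at 0.13–0.24 within sexes at n = 400, with
the ≥0.1 reporting flag set. Sign conventions of principal axes are arbitrary,
so directions are meaningful relative to the model's own convention.

The methods vignette (`vignettes/shape-modelling-methods.Rmd`) documents the
model, the tangent-space scoring construction, the statistical conventions,
the generator's calibration, and known limitations.

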