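# hsicolor

Chemometrics for visible/near-infrared **hyperspectral imaging (HSI)** of food
products, built around a concrete use case: predicting the core colour
(CIELAB L\*, a\*, b\*) of cooked sausages from push-broom reflectance cubes and
discriminating casing treatments from the measured colour. Everything a desk
analysis of such data needs is in one package:

- **Reflectance calibration** of raw counts against white/dark references,
  `R = (R_raw − R_dark) / (R_white − R_dark)`, with ENVI-style cube I/O.
- **ROI extraction and segmentation**: centred 50 × 50 pixel windows averaged
  into calibration spectra; sample/background segmentation by a strict
  reflectance threshold (0.05) at 690 nm (L\*) or 685 nm (a\*, b\*).
- **Spectral pre-treatments**: SNV, MSC, unit-area normalisation, and
  Savitzky–Golay first/second derivatives in physical units (per nm, per nm²).
- **PLS1 regression via NIPALS** (mean-centred, no variance scaling), with
  leave-one-out or k-fold cross-validation, RMSEC/RMSEP/RMSECV and
  R²c/R²p/R²cv, and the standard quality bands (≥ 0.66 acceptable, > 0.81
  good, > 0.90 excellent).
- **Wavelength selection**: backward elimination on the magnitude of the
  weighted regression coefficients (BW), retaining a small set of important
  optimal wavelengths (IOW) whose model matches the full spectrum within a
  cross-validation tolerance.
- **Pixel-wise colour maps** by unfold → predict → fold, with `NA`-sentinel
  background and linear colour scales.
- **Canonical discriminant analysis** of colour triplets by treatment group:
  eigenvalues, canonical correlations, Wilks' lambda (`Λ_k = Π_{i≥k} 1/(1+λ_i)`)
  with Bartlett chi-square tests, standardized coefficients, nearest-centroid
  classification, and one-way ANOVA with Tukey letter displays.
- A **synthetic scene and sample-set generator** with known ground truth
  (linear endmember mixtures with the 680 nm oxymyoglobin-type dip, seeded,
  exactly invertible calibration) so the entire pipeline is testable without
  instrument data.

## Worked example

```r
library(hsicolor)

grid    <- make_wavelength_grid()          # 380-1000 nm at 5 nm: 125 bands
samples <- simulate_sample_set(n_per_group = 30, noise_sd = 0.003, seed = 42)
split   <- split_samples(nrow(samples$spectra), fraction = 2/3, seed = 42)

ev <- evaluate_plsr(samples$spectra, samples$colours$L, grid,
                    treatment = "snv", max_components = 8,
                    split = split, cv_scheme = "kfold", k = 10, seed = 42)
data.frame(lapply(ev$metrics, round, 3))
#>  r2_c rmsec r2_cv rmsecv rmse_gap n_components  r2_p rmsep
#>  0.86 3.354  0.63  5.452    2.098            3 0.712 4.401
grade_model(ev$metrics$r2_c)
#> [1] "good"
```

The SNV-treated lightness model calibrates at R²c = 0.86 (RMSEC 3.35 L\*
units) with 3 latent variables and predicts the held-out third of the samples
at R²p = 0.71 — "good" calibration quality on the conventional scale.

```r
cda <- fit_cda(as.matrix(samples$colours), samples$groups)
cda
#> <cda_result> 2 canonical function(s), 3 groups
#>            eigenvalue variance_pct canonical_corr wilks  p_value
#> Function 1      0.347         89.4           0.51  0.71 5.97e-05
#> Function 2      0.041         10.6           0.20  0.96 1.78e-01
#> training classification rate: 50.00%

anova_letters(samples$colours$L, samples$groups)
#> one-way ANOVA p = 0.00138 (alpha = 0.05)
#>       group  mean   sd  n letters
#>     control 57.21 6.88 30       b
#>  treatment1 50.69 9.18 30       a
#>  treatment2 49.88 8.52 30       a
```

Colour separates the three casing treatments mainly along the first canonical
function (89% of the discriminable variance, Wilks' Λ = 0.71, p < 0.001), and
the control group's lightness is significantly higher than both treatments'
(letters `b` vs `a`).

For cube-level work (`simulate_scene` → `correct_reflectance` →
`segment_threshold` → `unfold_cube`/`map_attribute`) see the methods vignette
in `vignettes/`. A thin command-line front end with `simulate`, `calibrate`,
`preprocess`, `fit`, `select`, `map` and `discriminate` subcommands is
installed at `inst/cli/hsicolor`.

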