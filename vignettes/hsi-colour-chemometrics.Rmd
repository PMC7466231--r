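---
title: "Hyperspectral colour chemometrics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral colour chemometrics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsicolor)
```

## The problem

A push-broom visible/near-infrared imager records, for every spatial pixel of
a sample, a full reflectance spectrum — here 125 bands from 380 to 1000 nm at
5 nm intervals. For sausage cores stuffed in differently treated hog casings,
the questions are (i) can the interior CIELAB colour (L\* lightness, a\*
red–green, b\* yellow–blue) be predicted from the spectra, (ii) which few
wavelengths carry that information, (iii) what does the colour field look like
pixel by pixel, and (iv) does colour alone discriminate the casing
treatments? This package implements that workflow end to end, with a
synthetic-data generator providing ground truth for validation.

## Reflectance calibration

Raw counts depend on illumination and sensor gain. Calibration against a
white ceramic tile (`R_white`) and a closed-shutter dark frame (`R_dark`)
removes both:

$$R = \frac{R_{raw} - R_{dark}}{R_{white} - R_{dark}}$$

`correct_reflectance()` applies this elementwise and refuses any element
where `white − dark ≤ 0`. Because real acquisition software stores references
either as full frames or as per-band vectors, both are accepted and broadcast.
Out-of-range reflectance (below 0 or above 1.1, possible with specular pixels
or noise) is *retained* and only counted, never clipped — clipping happens at
map-rendering time. The correction is invariant to a common positive gain on
all three inputs, which the tests assert to 1e−12.

Cubes are stored in axis order (line, pixel, band), matching line-scan
acquisition, and serialised as a conventional ENVI-style ASCII header plus
flat binary (BIL/BIP/BSQ, float32 or float64, wavelengths in nm in the
header). Doubles roundtrip bit-exactly. No HDF5-style single-file container
is provided; the ENVI pair plus in-memory objects cover every use in the
package.

## ROI, segmentation and pre-treatments

Model calibration uses the mean spectrum of a 50 × 50 pixel window centred on
the sample (`extract_center_roi()`, floor convention on odd margins).
Pixel-level work uses threshold segmentation (`segment_threshold()`): a pixel
belongs to the sample when its reflectance at the attribute's band — 690 nm
for L\*, 685 nm for a\* and b\* — *strictly exceeds* 0.05. The band request
snaps to the nearest grid wavelength but only within half a grid step, so a
typo like 687 nm on a 5 nm grid errors rather than silently rounding.

Five pre-treatments are provided (`pretreat()`), all row-wise:

- **SNV** — centre and scale each spectrum to unit *sample* (n−1) standard
  deviation. The divisor convention is not universal; n−1 matches common
  chemometrics software and is what the idempotence tests assume.
- **MSC** — regress each spectrum on a reference and return
  `(x − intercept)/slope`. The reference defaults to the column mean of the
  matrix being treated, and is *frozen* when fitted inside a model so
  validation and pixel spectra are corrected against the calibration
  reference, not their own mean.
- **Normalisation** — interpreted as unit *trapezoidal area* over the
  wavelength grid, the reading under which spectra get "equal area under the
  curve"; max-norm and vector-norm variants exist behind the `method` flag
  but are not the default.
- **First/second derivative** — Savitzky–Golay filtering (`signal::sgolayfilt`),
  scaled by the band spacing to physical units (per nm, per nm²). Defaults:
  window 11 bands, polynomial order 2 (first derivative) or 3 (second). The
  source study names only "first and second derivative" without specifying
  the filter; Savitzky–Golay with these windows is the common choice, and
  both window and polyorder are arguments. Edges are handled by evaluating
  the fitted window polynomial at the edge positions, so band count is
  preserved. Derivatives are exact on polynomials up to the fit order
  (asserted to 1e−10).

## PLS regression

`fit_plsr()` implements single-response PLS (PLS1) by NIPALS: power
iteration with deflation of both blocks, convergence 1e−12 or 500 iterations
per component. X and y are mean-centred but not variance-scaled — the
chemometrics default for spectra, where band variance is informative. The
loadings are folded into one regression-coefficient vector per band (the
"BW" coefficients) plus an intercept, so prediction is a single matrix
product; this is also what pixel-wise mapping multiplies by. When noiseless
low-rank data exhaust the residual covariance before the requested component
count, extraction stops early rather than fitting numerical noise, and the
realised count is recorded.

Model quality uses the conventional quantities: RMSEC and R²c on the
calibration set, RMSEP/R²p on a held-out validation set (by default a seeded
uniform random 2/3 : 1/3 split, `split_samples()`; Kennard–Stone maximin
selection is available since the source protocol says only that samples were
"selected"), and RMSECV/R²cv by cross-validation (`cross_validate()`). The CV
scheme was not stated in the source study; the default is leave-one-out,
appropriate for n ≈ 90 samples, with seeded k-fold available for larger sets.
Any data-dependent pre-treatment statistic (the MSC reference) is re-learned
inside each training fold. The component count is chosen as the *smallest*
count whose RMSECV is within 2% of the global minimum — a parsimony rule of
our own choosing, since none is stated in the source; the 2% tolerance is an
argument. `grade_model()` encodes the usual quality bands: R² < 0.66
insufficient, 0.66–0.81 acceptable, 0.81–0.90 good, > 0.90 excellent.

## Wavelength selection

`backward_eliminate()` operationalises "discard a wavelength if its removal
does not significantly affect accuracy": candidates are tried in ascending
|BW| order (recomputed after each refit, i.e. dynamic rather than static
ranking, matching backward-selection semantics), and a removal is accepted
when the reduced model's re-optimised RMSECV stays within `(1 + tolerance)`
times the best RMSECV seen so far. The default tolerance is 5% — the source
study names no test or threshold, so this is a documented package decision
and an argument. The component count of each reduced model is re-optimised
by CV rather than inherited, preventing over-parameterisation once only 7–10
bands remain. Every attempted removal is logged (`criterion_log`), and with
a fixed CV seed the whole trajectory replays identically.

On the 125-band instrument grid, retaining 10, 10 and 7 bands — the sizes of
the published L\*, a\*, b\* selections — removes 92.0%, 92.0% and 94.4% of
wavelengths. The published band sets themselves cannot be re-derived without
the original images; `iow_from_wavelengths()` wraps them (or any external
list) as fixed selections for mapping.

## Pixel-wise mapping

`unfold_cube()` flattens the masked pixels (row-major, line by line) at the
selected bands; `predict_pixels()` multiplies by the model coefficients;
`fold_map()` writes predictions back to their positions. Background pixels
carry `NA` — 0 would be a legitimate a\*/b\* value — and rendering clips to the
recorded linear scale limits only at display time. Unfold/fold is bit-exact
and order-invariant (tested). One genuinely open question is whether
pre-treatments were applied per pixel before or after band subsetting in the
original workflow; `map_attribute()` applies full-spectrum transforms
(SNV, derivatives) to the complete pixel spectrum *before* selecting the IOW
columns, because derivatives and scatter corrections lose their meaning on a
7-band spectrum. This choice is visible in the function's documentation.

## Canonical discriminant analysis

`fit_cda()` forms the within-group (W) and between-group (B) scatter matrices
of the colour triplets and solves the generalized eigenproblem via a Cholesky
symmetrisation of W (numerically stabler than `solve(W) %*% B`, which the
tests use as the independent oracle). With g groups and p variables there are
min(g−1, p) functions. Conventions follow common statistical-package output:
raw coefficients scaled to unit pooled within-group score variance,
standardized coefficients = raw × pooled within-group SDs (the printed
equations' form), eigenvalue share as "variance (%)", canonical correlation
`sqrt(λ/(1+λ))`, Wilks' `Λ_k = Π_{i≥k} 1/(1+λ_i)` with Bartlett's chi-square
approximation for significance, and classification by nearest group centroid
in canonical space with equal priors. Whether the published function
coefficients are standardized or raw is not stated in the source; both are
exposed, and `evaluate_functions()` accepts an optional SD vector so either
reading can be computed.

`anova_letters()` runs one-way ANOVA per colour attribute and, when
significant, compresses Tukey HSD pairwise tests into a compact letter
display computed as the maximal cliques of the non-significance graph (exact
enumeration; treatment tables have few groups), lettered in ascending order
of group mean. Tukey HSD is our choice of post-hoc test; the source names
none.

## The synthetic-data generator

Because no images are deposited with the source study, the package ships a
generator whose defaults *are* the study conditions, used by all end-to-end
tests:

- `make_endmembers()` — smooth pure spectra: sigmoidal baseline rising into
  the NIR minus Gaussian absorption bands; the first endmember always has a
  band at 680 nm (the oxymyoglobin-type dip visible in sausage spectra), and
  its other random bands are kept off that dip's flanks so the local minimum
  is guaranteed. Values clipped to [0.05, 1].
- `simulate_scene()` — a centred elliptical "sausage slice" whose pixels are
  softmax-normalised smooth abundance fields mixing the endmembers, plus
  i.i.d. Gaussian reflectance noise inside the sample region; background is
  flat 0.02 reflectance (noise-free) so the 0.05 segmentation threshold
  separates it deterministically. Raw counts are re-encoded as
  `raw = dark + R · (white − dark)` with mildly spatially structured
  reference frames, making calibration exactly invertible: with zero noise,
  calibrating the scene with its own references reproduces the truth mixture
  to 1e−10. Truth colour is a full-rank linear map from abundances
  (`default_colour_model()`), so a k-component PLSR can recover it exactly.
  Abundances are `NA` outside the sample region and sum to 1 (1e−12) inside.
- `simulate_sample_set()` — per-group colour triplets from independent
  normals with the three casing treatments' published means/SDs (control L\*
  56.83 ± 5.48, etc.); only marginal SDs are published, so the within-group
  covariance is diagonal — an assumption, not source intent. Spectra follow
  a linear colour-to-spectrum link (`default_spectral_link()`: L\* moves the
  overall level, a\* the 500–650 nm region, b\* the blue end, each by a few
  percent reflectance per within-group SD) plus i.i.d. noise, default SD
  0.003 reflectance units — a typical post-averaging noise level for a
  50 × 50 ROI mean.

A single integer seed drives each generator through one documented stream
(endmembers: per-endmember baseline then bands; scenes: abundance fields,
then reference fields, then noise; sample sets: colours then noise), so every
object is bit-reproducible.

What the generator does *not* emulate: wavelength-dependent or spatially
correlated sensor noise (smile, keystone, shot noise), specular highlights,
casing rim effects, and — importantly — any nonlinear or non-Gaussian
structure linking colour to spectra. Passing tests therefore demonstrate
algorithmic correctness (calibration identities, exact recovery in noiseless
limits, selection of planted informative bands, statistical conventions),
not field performance on real sausages.

## Problem sizes and numerical choices

The test-suite simulations are deliberately small: toy matrices of 6–40
samples and 4–25 bands for algebraic oracles, 60 × 60 × 125 noiseless scenes
for end-to-end recovery (pixel-map maximum error < 0.01 L\* units), 12-band /
40-sample planted-signal problems across 20 seeds for backward elimination
(the two informative bands must survive in ≥ 95% of seeds), and n = 3000 for
the classification-rate convergence check against the analytic Bayes rate of
two spherical Gaussian groups. These sizes make every property cheap to
verify while leaving the algorithms identical at instrument scale.

Numerical edge handling worth knowing: constant spectra are rejected by SNV
(zero spread) and unit-area normalisation (zero area); `fit_plsr()` rejects
zero-variance responses and component counts above min(n−1, bands);
`backward_eliminate()` refuses negative tolerances; `fold_map()` degrades
gracefully to a half-unit scale around a constant map; BW ranking breaks
ties by ascending wavelength.

## Known limitations

- The published regression table values, band selections and the 62.90%
  classification rate derive from 89 real images that are not deposited;
  they are format templates and fixture constants here, not reproduction
  targets. The in-paper analytic identities (Wilks 0.64/0.92 and canonical
  correlations 0.55/0.29 from eigenvalues 0.43/0.09) are recomputed and
  asserted.
- PLS2, nonlinear regressors, and alternative selectors (CARS, SPA, VIP) are
  out of scope, as are vendor file formats and geometric/radiometric
  instrument corrections.
- CDA assumes a non-singular within-group scatter; collinear colour
  variables must be removed by the caller (the error message says so).
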