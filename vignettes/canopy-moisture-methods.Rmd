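---
title: "Methods: leaf moisture estimation from multispectral canopy imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf moisture estimation from multispectral canopy imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why
each default is what it is. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The estimation problem

Leaf moisture content (LMC) is the water fraction of leaf fresh mass,

$$\mathrm{LMC} = 100\,\frac{m_\mathrm{fresh} - m_\mathrm{dry}}{m_\mathrm{fresh}}\ [\%],$$

measured gravimetrically by oven drying (`leafMoisturePct()`). For
canopy crops around flowering it sits near 70 % and varies by a few
percentage points with irrigation and mulching. The package estimates
plot-level LMC from six-band canopy reflectance imagery (blue 450,
green 555, red 660, red edge 720 and 750, NIR 840 nm) through three
feature families — band-ratio vegetation indices, gray-level
co-occurrence (GLCM) texture statistics, and pairwise texture indices —
screened by correlation and fed to three small regression models.

# Pipeline stages and their assumptions

## Region means

`meanReflectance()` averages a band over the pixels whose *centers*
fall inside the plot polygon. Coordinates are image-style (origin
top-left, x along columns, pixel (r, c) centered at (c − 0.5, r − 0.5));
polygon vertices sit on integer coordinates, so a center is never on an
edge and the half-open convention is unambiguous — worth stating
because pixel counts at plot borders differ between conventions. Shadow
and soil pixels can be excluded with a reflectance floor on the NIR
band (`nirFloor`), a deliberately simple stand-in for the manual
exclusion a human operator performs; it is off by default.

## Vegetation indices

`computeVI()` implements the ten indices exactly as tabulated in the
crop-sensing literature this workflow follows, including two
transcription quirks that are exposed as flags rather than silently
"fixed":

* **OSAVI** is computed with the *green* band
  (`1.16 (R_NIR − R_G)/(R_NIR + R_G + 0.16)`). The index's original
  definition uses the red band; `osaviCanonical = TRUE` switches to it.
  The green-band form is the default so results line up with the
  tabulated convention this pipeline follows; the flag documents the
  difference instead of silently choosing.
* **MSAVI** uses the standard sign convention
  `0.5 (2R_NIR + 1 − sqrt((2R_NIR+1)^2 − 8(R_NIR − R_RED)))`;
  `msaviAsPrinted = TRUE` selects the ambiguous transcribed variant
  (leading `2R_NIR − 1` and a squared difference under the root).
* **RDVI** is read as `sqrt((R_NIR − R_RED)/(R_NIR + R_RED))` — the
  square root of a normalized difference; a negative radicand (NIR
  darker than red, i.e. non-vegetated) is an error, not NaN.

Which red-edge band serves as `R_RE` in MTCI and CI is configurable
(`redEdgeBand`, default band 4 at 720 nm — the conventional MTCI band).
All zero denominators raise errors naming the index; downstream code
never sees silent NaNs.

## GLCM texture

For each plot and band the region is quantized to 64 gray levels over
its own min–max range (`quantizeGray()`; the quantization source range
is configurable because acquisition software differs here), and a
co-occurrence matrix is accumulated in every 7 × 7 window at offset
(dr, dc) = (1, 1), counted symmetrically. Eight standard statistics
(mean, variance, homogeneity, contrast, dissimilarity, entropy with
natural log and 0·log 0 ≡ 0, second moment, correlation) are averaged
over all valid window centers (`regionTexture()`). Choices that affect
values and are therefore documented prominently:

* **Offset.** "Offset 1" is ambiguous between the horizontal (0, 1)
  and diagonal (1, 1) conventions; the default is (1, 1), the common
  remote-sensing default, and (0, 1) is available. Feature values
  differ between the two.
* **Edge handling.** Only windows lying fully inside the region (and,
  for polygonal regions, containing no masked pixel) contribute — no
  padding, no fabricated pixels. A region smaller than the window is an
  error naming the region.
* **Degenerate correlation.** A constant window has undefined GLCM
  correlation; such windows are excluded from the regional COR average
  and counted (`nCorUndefined` attribute). A fully constant region
  reports COR = 0 as an explicit sentinel.

The windowed accumulation is compiled (Rcpp); the exported
`cooccurrence()`/`textureFeatures()` give the same numbers one window
at a time, and the tests cross-check both against a naive
pair-enumeration oracle to 1e-12.

## Texture-index search

`searchFamily()` evaluates one of six pair-index families (ratio,
difference, sum, normalized difference, reciprocal difference,
reciprocal sum) on **every ordered pair** of the 48 texture features
(order matters for four of the six families), correlates each index
vector with moisture, and reports the pair with maximal |r| plus the
full r-matrix. Numerical conventions:

* Pairs are enumerated row-wise in band-major feature order and ties
  break to the first pair — output is deterministic.
* Pairs singular on any sample (zero denominator) or with zero index
  variance are skipped and counted, not fatal; only a family with *no*
  valid pair errors.
* The diagonal is excluded (NDTI ≡ 0, RTI ≡ 1 there).
* Because max-|r| over ~2 300 pairs inflates correlation under the
  null, an optional permutation test (`permutations = 999`, seeded)
  recomputes the family-wise maximum under shuffled moisture and
  reports `p_perm` for the best pair. It is off by default to mirror
  common screening-only practice.

By default the pipeline runs the search on the *training* samples only,
so that feature construction never sees validation moisture;
`paperFaithful = TRUE` searches all samples, which is how published
correlation tables of this kind are typically produced. Both modes are
provided because published analyses of this kind rarely state which
was used; the acceptance script uses the all-sample mode, and model
evaluation is unaffected in either mode by the train/validation split
of the regression stage.

## Screening and combinations

Every candidate feature is correlated with moisture (Pearson r,
two-sided t on n − 2 df, `pearsonWithP()`; Pearson rather than a rank
statistic because this workflow conventionally reports product-moment
coefficients) and
kept at p < 0.05. No multiple-testing correction is applied by default
— again mirroring common practice in this literature — with
Benjamini–Hochberg available (`adjust = "BH"`). Constant features
screen as non-significant instead of erroring, so degenerate scenes
flow through. The four model inputs are: significant vegetation
indices; significant textures; significant best-pair texture indices;
and their union, in that order. Empty combinations are kept with a
warning and refused by the model stage.

## Models

All three regressors use hyperparameter values conventional for this
workflow; where a choice was genuinely open, the defaults below are
the package's own documented decisions.

* **ELM** (`fitElm()`): 60 sigmoid hidden units (a wider 1000-unit
  variant, sometimes used for ELMs, is available via config), weights
  and biases uniform on [−1, 1], output weights by Moore–Penrose
  pseudoinverse on `[1 H]` (explicit intercept; rank deficiency is
  harmless). Inputs are z-scored with training statistics — bounded
  activations need comparable scales. 50 random restarts, keeping the best
  *training* RMSE: validation data are never consulted, so restart
  selection cannot leak.
* **XGBoost** (`fitXgb()`): 100 trees, learning rate 0.03, depth 5,
  squared-error objective, single-threaded for bit-reproducibility,
  all else at library defaults.
* **BPNN** (`fitBpnn()`): one hidden layer of 15 tanh units, linear
  output, Levenberg–Marquardt on sum-of-squares loss. The damping
  schedule is the standard one: mu starts at 1e-3, ×10 on a rejected
  step, ÷10 on acceptance, stop at mu > 1e10; additionally stop after
  300 accepted epochs or when SSE improves by < 1e-8 for 10 consecutive
  accepted steps (the stopping rule is the package's own default). Each step is solved in the thin-SVD
  basis of the Jacobian — exact, and fast in the
  parameters ≫ samples regime, where the step is the minimum-norm LM
  step. Inputs are z-scored and the response is standardized internally
  for conditioning (predictions are returned on the original scale).
  Accepted steps never increase the training SSE; the trajectory is
  stored and asserted in tests.

The train/validation split draws `round(2n/3)` samples (36/18 at the
default 54) with a seed; no stratification: a plain random split. Metrics: R² defaults to `1 − SS_res/SS_tot` (the conventional
validation form, which can be negative); the explained-variance form
`SS_reg/SS_tot` — equal for least-squares-consistent training fits,
sometimes reported for training accuracy — is available by flag. RMSE is in moisture
percentage points. MRE uses absolute relative errors: the signed form
would cancel to ≈0 for any unbiased model, which is incompatible with
MRE being co-reported alongside RMSE as a positive accuracy measure.

# The synthetic field trial

`simulateScene()` emulates the data-generating situation of a two-year
mulch × irrigation split-plot soybean trial; its defaults **are** the
study conditions of the package's tests and acceptance script.

* **Design**: 3 mulch levels (SM, FM, NM) × 3 irrigation levels
  (W1–W3) × 3 replicates × 2 seasons = 54 plot-season samples.
* **Moisture**: baseline 66 % + mulch effects (0, 1.5, 3) + irrigation
  effects (0, 2.5, 5) + N(0, 2) residual, clamped to (0, 100). The
  residual s.d. of 2 points is a realistic plot-to-plot spread; the
  treatment effects give a total s.d. ≈ 3, the spread implied jointly
  by the error magnitudes (RMSE ≈ 1.4) and accuracies (R² ≈ 0.8)
  reported for trials of this kind.
* **Reflectance**: per plot and band, mean = intercept + slope ×
  moisture, clamped to [0, 1]; at 70 % moisture the spectrum is
  canopy-like (NIR ≈ 0.45, red ≈ 0.05), wetter canopies brighter in
  NIR/red edge and darker in the visible. A mean outside [0, 1] before
  clamping is a configuration error.
* **Noise**: (i) per-plot, per-band calibration jitter
  (s.d. 0.002 reflectance) emulating residual illumination/calibration
  drift after whiteboard correction — this is what keeps the features
  from determining moisture exactly; (ii) per-pixel sensor noise
  (s.d. 0.01); (iii) a within-plot spatial field shared across bands:
  3 × 3 box-smoothed white noise with relative s.d.
  `textureLink × (moisture − 50)/25`, so wetter plots have stronger
  smooth structure. GLCM features of min–max-quantized data respond to
  the *ratio* of smooth field to white sensor noise, which this link
  makes monotone in moisture — that is the planted texture signal.
  Clamping after noise (rather than resampling) introduces negligible
  bias at these s.d. values.
* **Rasters**: plots are 21 × 21 px tiles in a gapped mosaic; one
  multi-page float32 TIFF plus GeoJSON plot polygons and a CSV moisture
  table round-trip through `writeScene()`/`readScene()` at float32
  precision.

What the generator does **not** emulate: real canopy geometry (rows,
gaps, soil background), radiative transfer, atmospheric or BRDF
effects, spatially correlated treatment gradients, or measurement error
in the oven-dried moisture itself. Passing tests therefore demonstrate
correctness of the computations and recoverability of a planted,
well-specified signal — not field performance of the method.

# Problem sizes in the tests

The unit suite runs on reduced scenes (9–17 px plots, one season) so
the whole suite completes in well under a minute; the acceptance-style
checks use the full 54-sample default trial, a 10 000-feature null
screen for type-I calibration, 100 replicates of the planted-pair
search recovery, and two full model grids (noise-free and noisy).
These sizes were chosen as the smallest that make the statistical
assertions sharp (e.g. the binomial s.d. of the null significant
fraction at 10⁴ features is ≈ 0.002 against a ±0.01 test band).

# Known limitations

* The ELM at its default width (60 units > 36 training samples)
  interpolates its training set; on noisy data its validation accuracy
  is accordingly erratic, and the test suite asserts its ranking
  behind the tree and LM-network models only in aggregate through the
  headline checks. This mirrors how such comparisons typically come
  out; an ELM with ridge regularization would behave better but would no
  longer be the standard ELM this package implements.
* GLCM features are computed per band with a single offset; the
  multi-offset averaging some software performs is out of scope.
* The exhaustive pair search reports selection-biased correlations by
  design (that is the method being implemented); the permutation
  adjustment is provided but off by default.
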