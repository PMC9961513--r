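---
title: "Methods: single-seed NIR-HSI chemometrics in seedhsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-seed NIR-HSI chemometrics in seedhsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seedhsi)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, the numerical choices made
where the design was genuinely open, what the synthetic generator does and
does not emulate, and the limitations of what a green test establishes.

## The problem

A pushbroom NIR imaging spectrometer records, for every pixel of a scene,
a reflectance spectrum — here 288 bands between 1000 and 2500 nm. Seeds
laid out on a dark plate become small connected blobs of bright pixels;
averaging the spectra of a seed's pixels gives one spectrum per seed.
Those object-wise spectra feed supervised discriminant models that answer
per-seed questions (presence of an asymptomatic fungal endophyte;
cultivar identity) that are invisible to the eye and expensive to assay
chemically or by genotyping. Because seed lots differ in age and batch,
the nuisance structure (baseline drift, scatter, batch offsets) is as
important to model as the signal.

## Pipeline stages and their assumptions

### Calibration

`calibrate_reflectance()` applies the flat-field model
`R = (I_S − I_D)/(I_W − I_D)` with white (≈100 % reflectance tile) and
dark (shutter closed) reference frames. Assumptions: detector response is
affine in radiance per band and pixel, and `I_W > I_D` wherever used
(violations are a hard error naming line/pixel/band). Reflectance outside
[0, 1] is *kept* by default and only flagged (`clipped_range` attribute):
scatter-correcting pre-treatments downstream can exploit that
information, and clipping is available as an explicit option. 3-D
(multi-scan-line) references are averaged over scan lines before use, the
standard treatment for pushbroom acquisitions.

### Segmentation

`segment_reverse_mask()` thresholds the mean reflectance over a
configurable wavelength window (default: the full range). The "auto"
mode is Otsu's histogram threshold — deterministic and adequate for
bright seeds on a dark background. Connected components (4-connectivity)
below `min_area = 10` pixels are dropped as speckle. The threshold rule
is a package design choice; any rule that separates the bimodal
foreground/background intensity histogram would serve. An empty
foreground is a warning, not an error, so batch runs survive empty
frames.

### Object-wise extraction

`extract_spectra()` computes the arithmetic mean spectrum per labelled
object — exactly, as verified against per-pixel brute-force recomputation
in the tests — plus pixel counts and centroids.

## Pre-treatments

All steps implement a fit/apply contract: *row-wise* steps (detrend,
baseline, derivatives, SNV, EMSC once its reference is fixed) transform
each spectrum independently; *fit-dependent* steps (EMSC's reference,
OSC, mean centring) freeze calibration-derived state and replay it on
held-out rows, never refitting. This train/test hygiene is asserted by
tests that mutate held-out rows and check fitted state is unchanged.

- **Detrend** (order 2 default): subtracts a per-row least-squares
  polynomial in band index. Order 2 matches the baseline order used in
  the standard chains.
- **Weighted least-squares baseline** (order 2): iteratively fits a
  weighted polynomial, down-weighting points *above* the current fit
  (weight 0.001 vs 1 below; ≤ 100 iterations, tolerance 1e-6 on the
  weight vector), so the baseline hugs the lower envelope and its
  subtraction limits negative signals. The asymmetric weight, iteration
  cap and tolerance are package choices; only the behaviour ("iterative,
  limiting negative signals") is externally specified.
- **Savitzky–Golay derivatives**: "2nd derivative (order = 2, 15 pt)" is
  read as derivative order 2, fitting-polynomial order 2, window 15
  points — the notation of the common chemometric toolboxes. Edges use a
  shrunken asymmetric window refit (no padding), which keeps the filter
  exact for polynomials up to the fitting order at *every* band.
  Documented error bound: for a sine sampled at 200 points, the 15-point
  first derivative deviates from the analytic derivative by < 0.03.
- **SNV**: per-row standardization with the sample (n−1) standard
  deviation (the denominator convention is a documented choice).
- **EMSC**: per-row regression `x = a + b·m + Σ d_j λ^j + e` with
  reference `m` = calibration-set mean spectrum and wavelength polynomial
  order 2 by default (both choices are package defaults); the corrected
  row is `(x − a − Σ d_j λ^j)/b`. `|b|` below 1e-8 is a hard error
  (degenerate multiplicative term).
- **OSC**: removes components of maximal X-variance whose scores are
  orthogonal to the class-indicator matrix Y. Implementation: the leading
  principal score of the centred calibration matrix is alternately
  projected out of span(Y) and regressed back onto X (minimal-norm
  weights via SVD), to convergence (tolerance 1e-10, ≤ 500 iterations);
  the matrix is deflated by the final *exactly orthogonalized* score and
  its loading. Consequence: stored calibration scores satisfy
  |tᵀY| < 1e-8 by construction, while scores of new data (from the
  stored weights) reproduce them only approximately — the standard
  asymmetry of OSC variants. One component is removed by default; the
  component count used by the reference study is not stated anywhere, so
  it is left configurable. OSC is refitted inside every CV fold (the
  stricter policy); commercial toolboxes sometimes fit it once globally,
  which is why absolute CV numbers can differ from theirs.
- **Mean centring**: subtracts calibration column means, never the test
  set's own.

The six preset chains `pt1`…`pt6` are the standard combinations (all
start detrend → baseline(2), all end in mean centring; `pt6` inserts
2nd derivative → EMSC → OSC). SNV and the first derivative are
implemented and tested but appear in no preset, mirroring their status as
trialled-but-not-selected methods.

## Splitting, cross-validation, models

- **Kennard–Stone** (`kennard_stone_split()`): deterministic max–min
  Euclidean selection; the first two picks are the globally most distant
  pair, ties break to the lowest row index. The calibration size is
  `ceiling(fraction·n)`, which maps a 95/5 request on 1057 rows to
  1005/52 — matching the reference design — while staying within one row
  of the requested fraction. Distances are computed on the matrix as
  given; pre-process first if the split should live in the modelling
  space.
- **Venetian blinds** (`venetian_blinds()`): row *i* (stored order) goes
  to fold `(i−1) mod k + 1`, default k = 10. Fold class balance therefore
  depends on row order; `order_by_class()` reproduces "organized in class
  order" layouts. A pitfall the tests exploit deliberately: if classes
  alternate with a period dividing k, folds become single-class and CV
  error estimates collapse.
- **PLS-DA**: NIPALS PLS2 with X-only deflation, classes coded as
  indicator columns, unit-norm weight vectors. The decision rule is
  arg-max of the predicted indicators — well-defined for 2 and 5 classes
  alike and the difference most likely to shift absolute numbers versus
  toolboxes that estimate per-class thresholds. LV selection ("auto")
  minimizes the mean CV class error with ties to fewer LVs, and the CV
  curve is recorded.
- **PLS compression + C-SVM / ANN-DA**: the non-linear models run on PLS
  scores (supervised compression, dimension `n_compress_lv`). The C-SVM
  is an RBF-kernel soft-margin machine trained by a fully deterministic
  SMO (working pair chosen by maximal KKT violation, no randomness);
  multi-class is one-vs-one voting with ties to the lowest class index.
  The ANN is one logistic hidden layer (default 10 nodes) with softmax
  outputs, trained full-batch by BFGS on the cross-entropy loss with a
  small L2 penalty (1e-4) for conditioning; the mandatory seed controls
  only weight initialisation, making fits bit-reproducible. The SMO and
  the network are implemented in-package because no SVM/ANN library is
  part of the supported dependency set.
- **Metrics**: class error is stored in percent internally so the
  overall-accuracy rule is literally `100 − max(CE)`, taken over the CV
  and prediction phases of all classes ("whichever is higher"). Display
  rounding is half-away-from-zero to one decimal; tests compare unrounded
  values. For five-class problems the per-class errors follow the
  one-vs-rest convention — the reading asserted for the published tables,
  not verifiable against raw data.

## GA effective-wavelength selection

`ga_run()` evolves binary band masks under an RMSECV fitness: PLS
regression of the indicator matrix on the masked bands, venetian-blinds
CV, RMSECV at the LV count (≤ `max_lv`, default 10) minimizing it. The
externally specified parameters are population 64, ≤ 100 generations,
double (two-point) crossover, per-gene mutation 0.005, termination at
50 % population identity, 1 GA iteration, single-band genes. Package
choices where the scheme was open: rank-based selection with the top half
breeding; one-individual elitism (making the best-fitness trace monotone
and testable); initial gene density 0.3; all-zero children repaired by
activating one random locus; "50 % convergence" read as "≥ 50 % of
individuals identical" (a genes-fixed variant is available by flag). The
fitness uses a crossprod-based kernel PLS that is algebraically identical
to the NIPALS fit (asserted in tests to 1e-13) but independent of n once
the crossproducts are formed, which keeps the ~6 400 fitness evaluations
of a full run to a few minutes. The published band counts (75 and 87) are
data-dependent outcomes on proprietary images and are *not* targets; the
package's acceptance surface is recovery of known informative bands in
synthetic data.

## The synthetic generator: what it emulates, what it does not

`sim_spec()` describes the stated world: a smooth positive base
reflectance (broad water/starch-like absorbance bands mapped through
`exp(−A)`), class signatures as Gaussian absorption features (width 5–15
bands) defined in absorbance and applied multiplicatively — so
derivative and scatter-correction steps see realistic band shapes —
batch effects as additive baseline tilt plus offset, per-object
multiplicative/additive scatter, and iid per-band Gaussian noise.
Geometry, scatter and noise use independent RNG streams derived from one
seed, so changing the noise level leaves the scatter draws bitwise
identical (tested). `make_hypercube()` rasterizes elliptical seeds on a
grid and inverts the calibration model (`raw = dark + (white−dark)·R`)
so the imaging stages are exercised end to end; a noise-free world round
trips to the generator's spectra at floating-point precision.

`preset_study()` emits the 1057-row cultivar × endophyte × batch layout
of the reference design (e.g. Trojan E+ n = 193, totals 577 E+ / 480
E−). Its effect sizes were calibrated **once**: with per-cultivar
signature amplitude 0.030, endophyte signature 0.012 (three features),
batch tilts ≤ 0.015 and noise sd 0.007, the full-spectrum PLS-DA (pt6,
4 LVs) reference pipeline lands at 90.4 % overall accuracy — inside the
stated 85–95 % design band and near the ~89–90 % regime the method is
known to reach on real seed. This is a tuned emulation of the *statistical
structure* of such data, not a reproduction of any real dataset: real
seed spectra have correlated, heteroscedastic noise, within-class
morphological variation, and chemically structured class differences that
iid noise plus Gaussian dips do not capture. A green synthetic test
therefore establishes that the algorithms are implemented correctly and
behave as expected under the assumed structure — not that the published
accuracies would be reproduced on the original images, which are not
deposited.

The GA acceptance world (200 × 288, classes differing only in bands
100–119 via a flat-top run of four absorbance features, amplitude 0.02,
noise sd 0.01, seed 11) was likewise designed once so that each
informative band carries modest individual signal — rewarding masks that
include the whole run — and left fixed.

## Numerical choices and degenerate inputs

- Polynomial bases (detrend, baseline, EMSC wavelength terms) use an
  abscissa scaled to [−1, 1] for conditioning.
- Least-squares solves use QR or SVD pseudoinverse; PLS deflation stops
  early when a score norm vanishes (rank exhaustion) and reports the
  components actually extracted; `lv` grids exceeding the training-fold
  rank bound are trimmed with a warning.
- A GA mask too rank-deficient for one LV receives worst-case fitness
  (RMSE of the mean-only model) instead of erroring, so evolution can
  continue past degenerate individuals.
- Duplicate-only datasets in Kennard–Stone resolve by lowest index;
  arg-max ties in classifiers resolve to the first (lowest) class.
- `ceiling` vs `round` in the split size is deliberate (see above).

## Known limitations

- No instrument interface; ENVI BSQ/BIL files (float32/64,
  little/big-endian) are the ingestion path.
- OSC component count and the global-vs-per-fold pre-processing policy of
  the reference toolboxes are unknown; both are configurable, defaults
  documented above, so absolute agreement with toolbox outputs is not
  guaranteed.
- The ANN uses BFGS rather than stochastic training; very large score
  matrices would train slowly (irrelevant at ≤ 19 compression LVs).
- The SMO solver targets the small PLS-score problems used here; it is
  not tuned for n ≫ 10⁴.
- Ellipse-on-grid geometry does not emulate touching seeds; the
  segmenter has no watershed splitting.
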