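---
title: "Methods: sequential multiblock calibration of fused MIR/XRF soil spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential multiblock calibration of fused MIR/XRF soil spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Proximal soil sensing aims to replace slow laboratory chemistry with
spectroscopic prediction of fertility attributes — pH, organic carbon
(OC, %), extractable P, K, Mg and Ca (mg/100 g), and moisture content
(MC, %). Two sensors see different physics: mid-infrared (MIR)
absorbance over 4000–650 cm⁻¹ responds to molecular vibrations of
organic matter, water and minerals, while X-ray fluorescence (XRF)
counts over 0–30 keV respond to elemental composition. Neither sensor
alone carries all the information, so this package implements
*low-level spectra fusion*: the two spectra are concatenated and
modeled jointly, and the central question is whether — and how — the
fused model beats the better single-sensor model.

Five model families are compared on one shared calibration/validation
split:

* **MIR-TPLS**, **XRF-TPLS** — traditional PLS on one block;
* **SF-PLS** — PLS on the concatenated channels;
* **SF-SOPLS** — sequential orthogonalized PLS, MIR first, XRF second;
* **SF-VIP-SOPLS** — SOPLS on the channels whose variable importance in
  projection exceeds 1.

## Models

### NIPALS PLS

`fit_pls()` mean-centers `X` (n × p) and `y` and extracts latent
variables by NIPALS: unit-norm weight vectors `w_a`, scores
`t_a = X_a w_a`, loadings `p_a = X_a't_a / t_a't_a`,
Y-loadings `q_a`, with deflation `X_{a+1} = X_a − t_a p_a'`. The
decompositions are `X = T P' + E` and `Y = U Q' + F`; predictions use
`B = W (P'W)⁻¹ Q'` plus the stored centers. Channels are centered but
not autoscaled — all channels of a spectrum share one unit, and
autoscaling would inflate noise channels. NIPALS is used rather than
SIMPLS because the VIP statistic is defined on the per-component
weights `W`. If deflation exhausts the usable rank before the requested
component count, fitting truncates with a warning.

The component count is chosen by k-fold cross-validation
(`select_lv()`): contiguous fold blocks after one seeded shuffle,
RMSECV per candidate count, argmin with ties going to the smaller
count. The default is 10 folds and a cap of 20 components (tests and
examples use smaller caps matched to their sample sizes); both are
arguments. All fold statistics — centers, weights, any preprocessing
reference — are learned inside the training fold only, and
`keep_pred = TRUE` exposes the out-of-fold predictions so leakage can
be audited directly (a sample's out-of-fold prediction must not change
when its own response is corrupted).

### Sequential orthogonalized PLS

`fit_sopls()` implements the two-block sequential model
`Y = X₁B₁ + X₂C₂ + E`:

1. fit PLS(`X₁`, `Y`) with `a₁` components, keeping scores `T₁`;
2. orthogonalize the centered second block against the score space,
   `X₂ᵒʳᵗʰ = X₂ᶜ − T₁(T₁'T₁)⁻T₁'X₂ᶜ` (pseudo-inverse with tolerance
   1e−10, robust to near-collinear scores);
3. fit PLS(`X₂ᵒʳᵗʰ`, `Y − Ŷ₁`) with `a₂` components;
4. predict by summing both stages: `Ŷ = T₁Q₁' + T₂ᵒʳᵗʰQ₂'` plus
   centers.

Two properties make this attractive for heterogeneous sensors, and both
are enforced by tests: predictions are invariant to rescaling either
block (each block enters only through its own scores), and the second
block's contribution is strictly incremental (its channels are
projected out of the stage-1 score space, so shared information is
never counted twice). Setting `a₂ = 0` recovers plain PLS on block 1
exactly; `a₁ = 0` defers everything to block 2. MIR is taken first by
default — it is the more informative sensor for these attributes — but
the argument order is the block order, so this is overridable.

`sopls_select_lv()` chooses `(a₁, a₂)` by exhaustive grid search (the
selection strategy is otherwise a free design choice; a full factorial
is reproducible and cheap at these sizes), re-learning the
orthogonalizer and both stage fits inside every fold. Ties go to
smaller `a₁ + a₂`, then smaller `a₁`.

### VIP selection

For a fitted PLS model, `compute_vip()` scores channel `j` as

VIP_j = sqrt( p · Σ_a w_ja² · SSY_a / SSY_tot ),

with `SSY_a = (t_a't_a) q_a²` the Y sum of squares explained by
component `a`. With unit-norm weights the mean squared VIP is exactly
1, which motivates the conventional threshold of 1: a channel scoring
above it is "more important than average". The threshold rule is
strict (`>`), so a flat model in which every channel scores exactly 1
selects nothing — this boundary is documented and `>=` is available.
`fit_sf_vip_sopls()` computes VIP per block from that block's own
CV-selected PLS model (the defensible reading of scoring each sensor's
channels by its own fit; VIP on the fused SF-PLS model can be had by
calling `compute_vip()` on such a model), masks each block, and refits
SOPLS on the reduced blocks with a fresh grid search. Every selection
statistic comes from training data only.

### Evaluation

`rmse()`, `r_squared()`, `rpd()` and `rpiq()` follow the standard
conventions: R² is `1 − SS_res/SS_tot` (the complementary as-printed
ratio is available as `residual_ratio()`; the two always sum to 1),
RPD divides the `n − 1` standard deviation of the measured values by
the RMSE, and RPIQ divides the interquartile range using the
linear-interpolation quantile convention (`stats::quantile` type 7,
pinned in tests; the convention shifts RPD/RPIQ only in the second
decimal at n = 40). A zero RMSE yields `Inf` with a warning rather
than an error.

## Preprocessing

Operators are row-wise, never change sample count or order, and accept
a `spectra_block`, a matrix or a bare vector:

* `moving_average(window = 5)` — centered mean; edges use the
  shrinking-window rule (mean over the available neighbors).
* `max_normalize()` — divide by the per-spectrum maximum; idempotent.
* `snv()` — per-spectrum standardization (`n − 1` denominator);
  exactly idempotent and affine-invariant.
* `msc(reference)` — OLS of each spectrum on a reference (default: the
  mean spectrum); returns `(x − â)/b̂`. In calibration the reference is
  learned on the training set by `fit_recipe()` and frozen.
* `savitzky_golay(window = 11, polyorder = 2)` — delegated to
  `signal::sgolayfilt`; reproduces polynomials of degree ≤ order.
* `baseline_correct(smoothness = 1e5, asymmetry = 0.01)` — asymmetric
  least squares with a second-difference penalty, the standard choice
  when the baseline method itself is not prescribed; parameters are
  exposed and the defaults flatten a smooth ramp to ~0 while keeping a
  narrow peak's height within 5%.
* `compton_normalize(window = c(18, 22))` — divide by the trapezoidal
  integral over the scatter window. The window is configurable; the
  default brackets the Rh K-line scatter region of a Rh-anode
  instrument near 20 keV.
* `drop_channels(interval = c(2.3, 2.7))` — excise detector artifacts
  such as a spurious peak near 2.5 keV.

`recipe_preset(sensor, attribute)` returns the per-attribute chains
used for the soil attributes — moving average then max-normalization
for pH/OC/Mg/MC, SNV for P, nothing further for K, MSC for Ca, with
XRF recipes prefixed by baseline correction and Compton normalization.
Savitzky–Golay is provided as an operator but appears in no preset, as
the presets follow the per-attribute chains exactly.

## Kennard–Stone partitioning

`kennard_stone()` is the deterministic max–min algorithm on Euclidean
distances: seed with the most distant pair, then repeatedly add the
candidate whose minimum distance to the selected set is largest. Ties
break toward the lowest sample index, so the split is a pure function
of the input matrix. The training size is `floor(fraction · n)` — 80%
of 196 samples gives exactly 156/40. Whether distances should be
computed on raw or preprocessed, single-block or fused spectra is not
prescribed anywhere authoritative, so the function takes whatever
matrix it is given; `run_comparison()` uses a per-spectrum-only
reference preprocessing of the fused spectra so that all five model
families share one split, which is what makes the comparison fair.

## The synthetic generator

No field data accompany this workflow, so `generate_soil_data()`
produces a statistically analogous stand-in. Its defaults are the
study conditions: 196 samples, 900 MIR channels over 4000→650 cm⁻¹,
2048 XRF channels over 0→30 keV.

* **Latent chemistry.** `n_latents` factors per block (default 3),
  drawn U(0.5, 1.5): concentrations fluctuate ~29% around a common
  level, as real soil constituents do. The MIR-visible and XRF-visible
  groups are disjoint, which is what makes cross-sensor
  complementarity possible at all.
* **MIR block.** Each latent loads on Gaussian absorption bands placed
  inside the windows 3800–3000 (O–H stretch), 3000–2820 (C–H), 1873 and
  1730 (C=O), 1632–1530 (O–H/C–H), 1409 and 1157 cm⁻¹ (fingerprint),
  on top of a constant broad mineral-matrix background
  (`mir_background`). The background matters structurally: it makes
  spectra affine rather than homogeneous in the concentrations, and
  without it per-spectrum normalization would remove the
  total-concentration degree of freedom entirely. Per-sample
  multiplicative gain and additive offset (scale `scatter_sd`) emulate
  scatter; additive Gaussian noise has SD `noise_sd["mir"]` in
  absorbance units. Setting `mir_background = 0`, `scatter_sd = 0`,
  `noise_sd = 0` yields a block that is exactly latent-spanned (rank
  `n_latents`), which the tests exploit.
* **XRF block.** Latents load on emission lines (Mg 1.25, P 2.01,
  K 3.31, Ca 3.69, Fe 6.40/7.06 keV, plus heavier-element peaks in the
  13–17 and 25–28 keV regions) over a bremsstrahlung-like continuum
  with a weak Rh-scatter bump near 20 keV and a detector-noise spike at
  2.5 keV. Noise is variance-proportional Gaussian — a Poisson
  surrogate with closed-form moments. Both spectra families are
  truncated at zero after noise.
* **Attributes.** Each attribute is
  `mean + sd · (√(1−c)·z₁ + √c·z₂ + ε)/norm`, with `z₁`, `z₂`
  standardized signals from the MIR and XRF latent groups,
  `c = complementarity` the fraction of signal variance carried only by
  the XRF block, and `ε` sized by `attr_snr` (default signal-to-noise
  10; `Inf` gives exactly linear attributes). Loadings carry random
  signs — attributes rise with some constituents and fall with others —
  so the signal is not collinear with total concentration. Target
  means/SDs are patterned on descriptive statistics of agricultural
  topsoils, with SDs shrunk where necessary so that 3.5 SD below the
  mean stays above the observed minimum (keeping skewed nutrients such
  as P positive under a linear model).

What the generator does *not* emulate: spatial correlation among field
samples (samples are exchangeable), instrument drift, nonlinear
detector response, particle-size effects beyond affine scatter, and
real covariance between soil attributes. Passing benchmarks on this
generator therefore demonstrates that the algorithms recover planted
structure under realistic noise, scatter and information-splitting —
not that any particular field accuracy would be achieved.

## Numerical choices

* NIPALS convergence/rank tolerance 1e−12 (relative); score-projection
  pseudo-inverse tolerance 1e−10.
* CV ties → fewer components (PLS) or smaller `a₁+a₂` then smaller
  `a₁` (SOPLS); Kennard–Stone ties → lowest index.
* `attribute_ranges()` reports SD = 0 for a single sample.
* Degenerate inputs are errors with named context: constant spectra in
  SNV, zero MSC slope, non-positive maxima, empty VIP selections,
  folds of fewer than two samples.

## Problem sizes used in the shipped checks

The test-suite benchmarks run at deliberately modest sizes chosen to
exercise the full workflow many times over: 20 seeded replicates of
96 samples × (120 + 160) channels for the fusion comparison, 5
replicates for the no-gain limit at complementarity 0, and 20
replicates of 100 × 500 for VIP support recovery. The dataset-scale
facts (156/40 split of 196 samples, 900 + 2048 = 2948 fused variables)
are checked at full width. These sizes are the package's own choice of
benchmark scale; every threshold asserted by the suite is stated in the
tests themselves.

## Known limitations

* Two blocks only; three-block sequential fusion and PO-PLS variants
  are out of scope.
* Single-response fits are the default throughout the pipeline (each
  attribute modeled separately); `fit_pls()` itself accepts
  multi-response `Y`.
* The ALS baseline is a generic smooth-baseline estimator, not a
  physical continuum model.
* Kennard–Stone is the only partitioner (no Duplex/SPXY).
* With `complementarity = 0.5` and SNR 10 the per-block ceiling on
  predictable variance is ~0.45 R², so absolute accuracies on synthetic
  data are not comparable to field-data reports; only the *ordering* of
  model families is.
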