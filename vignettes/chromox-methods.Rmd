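---
title: "Methods: smartphone colorimetry and the skin-tone correction system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone colorimetry and the skin-tone correction system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromox)
```

# The measurement problem

A colorimetric assay photographed with a phone confounds the quantity of
interest (dye absorbance) with the ambient illumination, the shooting
distance, the camera's automatic exposure and the background. An image-based
oximeter adds a physiological confound: melanin absorbs across the visible
spectrum, so both pulse oximeters and lip-color models systematically err on
darker skin. `chromox` treats the two problems with the same toolkit — an
illumination-invariant color quantifier, explicit inversion of the camera's
corruptions, and linear correction models trained against reference
instruments — and validates everything against a forward simulator in which
the ground truth is known exactly.

# The SCQP quantifier

For an 8-bit pixel, HSV value is `V = max(R,G,B)` and saturation is
`S = 1 − min/max`. The *strongly correlated quantitative parameter* is the
ratio `G/V`; its complement

$$\mathrm{signal} = 1 - G/V$$

equals `S` exactly whenever G is the minimum channel (a red-family dye on a
light substrate) and remains monotone in concentration elsewhere. Two
properties make it robust:

1. **Illumination invariance.** A multiplicative illumination change scales
   every channel equally, so the ratio cancels. Gamma encoding is a power
   law and therefore preserves multiplicativity — the cancellation holds in
   encoded (display) space too, not only in linear-light space.
2. **Range extension.** Saturation-only quantification deviates at low
   concentration; `1 − G/V` is the same quantity expressed through the
   dominant channel and stays near-linear in concentration over the
   working range when channel absorbance is small (see the dye-map choice
   below).

The identity `S/100 = 1 − G/V` for G-minimum pixels is asserted to machine
precision over 10^4 random colors in the test suite; SCQP scale invariance
is asserted over multiplicative factors in (0, 1].

Conversions are convention-pinned so results are comparable across devices:
hue in degrees, S/V in percent; CIELAB via sRGB primaries, D65 white and
the 2° observer (values frozen against an independent reference
implementation to 0.1); grayscale via ITU-R BT.601 weights
(0.299, 0.587, 0.114). Real cameras deviate from sRGB; that deviation is
handled downstream by the color-correction models, never by re-pinning the
conversion.

# Image evenness calibration

Uneven illumination is estimated with a multiscale Gaussian surround of the
V matrix: `L = mean_σ(kernel_σ ∗ I)` with equal weights over the scales,
and corrected by deviation equalization

$$N = \mathrm{clip}(I + k\,(L_{avg} - L),\ 0,\ 1), \qquad k = 1 - \mu .$$

Choices that matter:

- **Scales** `σ = 20, 72, 250` px (default) balance dynamic-range
  compression against detail for full-resolution phone frames; they must be
  scaled with image size. The package's synthetic frames are 368 px across,
  so the examples and tests use the proportional set `σ = 4, 13, 45`.
- **`k(μ)` form.** The published description fixes only the contract —
  μ ∈ [0,1], smaller μ calibrates more, `L_avg` is the target level. The
  package uses the simplest form meeting it, `k = 1 − μ`: μ = 1 is exactly
  the identity and μ = 0 is full flattening `I − L + L_avg`. The calibration
  degree (IQR reduction of V on a gradient scene) is asserted to be monotone
  nonincreasing in μ.
- **Only V is touched.** Each pixel's channels are rescaled by `N/V`, which
  preserves the channel *ratios* and hence hue and saturation bit-exactly;
  the image is then re-encoded from the equalized values.
- **Boundaries.** Reflective padding avoids the edge darkening of zero
  padding; kernels are truncated at 3σ and renormalized to unit mass
  (`C = 1/ΣF`). Images smaller than the kernel support are an explicit
  error rather than a silent extrapolation.

On a flat-reflectance scene under a lateral illumination gradient, μ = 0
reduces the within-image V range by ≈86 %. The residual is an edge effect:
reflection flips the gradient's slope, so the surround deviates from the
image within ~σ of the border.

# Shooting-distance calibration

The camera applies `G = 255·(D/255)^{1/γ}` between linear sensor signal D
and displayed value G. Distance correction operates in linear-light space:
decode with γ (default 2.2, admissible 2.0–2.2, device-dependent), scale by
the exponential distance model

$$C_{D2} = D_2 \cdot \tau^{\Delta \mathrm{Distance}/5},$$

with amendment factor τ = 1.1 per 5 cm step, clip, and re-encode. The
simulator attenuates with the same exponential family, so calibration
inverts rendering *exactly* (residual ≤ 1e−14 in linear channels) in the
noise-free limit — a deliberate closure property. Real optics follow an
inverse-square-with-aperture law that this family only approximates over
small ΔDistance; the exponential form is the one the calibration
literature fits empirically, and the agreement metric (mean |D1 − C_D2|)
is exposed so τ can be re-fitted per device.

# Chip segmentation and signal extraction

Grid detection is deliberately dependency-light: grayscale → Sobel gradient
magnitude → Otsu threshold → morphological closing → hull filling →
connected components → 1-D k-means (deterministic quantile initialization)
on the centroid rows and columns. It requires exactly 36 components forming
a full 6×6 grid and reports the count found otherwise. Sampling boxes cover
the inner 60 % of each groove (0-based, half-open, row-major), and the
recipe tolerates the small in-plane rotations a handheld shot produces
(tested at 2°).

The artifact filter on a groove's pixels works on brightness V in two
stages: a symmetric rank-based 5 %/5 % tail trim (on a uniform box this
rejects the nominal ~10 %, giving a well-defined behaviour under ties),
then a robust screen rejecting survivors more than `3·max(MAD, 0.005)` from
the surviving median. The second stage is what removes artifacts too wide
for the tails — a 10 % saturated-glare plateau or a 20 % shadow band leave
the surviving mean within 1–2 8-bit units of the true dye color in the test
fixtures. Grooves with fewer than 25 usable pixels, or more than 80 %
rejection, are errors, not numbers.

Quantification is ordinary least squares of concentration on signal over at
least 3 distinct standards, with extrapolation beyond the calibration range
flagged per sample.

# Regression machinery

All fitting is first-party and seeded; fits are bit-reproducible given
(data, spec, seed).

- **MLR/PR (Lasso).** Objective `1/(2n)·Σr² + α·Σ|w|` with α = 0.1 and the
  subgradient of |w| taken as 0 at 0; the intercept is unpenalized. PR maps
  each feature to `[x, x²]` first. The 1-D solution is soft-thresholded OLS,
  `soft(ŵ, α·n/‖x‖²)`, which serves as the closed-form oracle.
- **SVR.** Primal `½‖w‖² + C·Σ(ζ+ζ*)` with linear kernel, C = 1.5, ε = 1,
  optimized via the per-sample-normalized subgradient (`w/n` plus the
  ε-insensitive term). Predictions agree with an established reference
  implementation to <1e−4 RMS on the 50-point oracle set. Shrinkage of the
  slope below the generating value on narrow feature ranges is the true
  optimum of this objective, not an optimization failure; the wide-range
  construction recovers the slope.
- **DTR.** Variance-reduction CART, depth ≤ 3, leaf mean prediction,
  midpoint thresholds, ties resolved to the lowest feature index then the
  lowest threshold. Split decisions depend only on feature order, so
  predictions are invariant to strictly monotone feature rescalings.
- **NN.** 5→64→32→16→5→1 with ReLU hidden units, squared-error loss, He
  initialization, minibatch SGD, early stopping when the validation loss
  (20 % seeded holdout) has not improved for 15 epochs, best weights
  restored.
- **Logistic.** Cross-entropy by SGD with probabilities clipped to
  `(1e−12, 1−1e−12)`.
- **Optimization defaults.** Learning rate 0.01 with 1/t decay, 500 epochs,
  batch size 16, seed 20240101 — all configurable. Oracle comparisons use
  full-batch descent with more epochs; convergence to a kinked optimum at
  1e−4 needs the noise floor that minibatching would leave. The reported
  weights are the tail average of per-epoch iterates (last 25 %), which
  damps SGD chatter without biasing the optimum.
- **Cross-validation.** Deterministic shuffled partition into K = 10 folds
  with sizes differing by ≤1; standardization parameters are learned inside
  each training fold only (the fit objects carry their own scaling), so no
  information leaks into validation folds.

# The correction system

The interconnected workflow on a cohort:

1. **Oximeter correction.** Gold-standard SpO₂ (A) is modeled linearly on
   the oximeter index F, the spectrophotometer tone L\*, a\*, b\* and the
   melanin index `M = 100·log₁₀(1/R₆₅₅)`; the corrected oximeter value is
   the model prediction, clipped to [0, 100].
2. **Color correction.** Four linear models map the imaged tone
   (L\*ₛ, a\*ₛ, b\*ₛ, Gₛ, Bₛ) plus the camera setting (log₂ ISO, or
   brightness V where ISO is unavailable) onto L\*, a\*, b\*, M.
3. **App model.** Lip color features plus corrected tone predict the
   *corrected* oximeter reference; pCO₂ uses the same machinery against its
   own features and labels.

Eq-structure fits use Lasso-SGD for support selection followed by an OLS
refit on the selected features (relaxed lasso). The refit is what makes the
system auditable: in the noise-free limit the generating weights are
recovered exactly (the raw Lasso optimum is soft-thresholded by
construction and cannot be), while the selection stage still prunes inert
features under the published α = 0.1.

**Noise-based training.** For the app and pCO₂ models, an exactly-20 %
seeded subset of training rows receives additive Gaussian feature noise
with sd equal to 10 % of each feature's standard deviation (the published
description fixes the 20 % fraction but not the distribution; a
feature-scaled Gaussian is the neutral choice). The injection mask is
recorded in the fit object.

**Classification.** SpO₂ ≤ 95 % is "low"; the monitoring bands are <95,
[95, 97), [97, 100]. Bland–Altman agreement uses the
method-under-test-minus-reference sign convention with LoA = bias ± 1.96·SD.

# What the simulator emulates — and what it does not

The camera model composes, in order: multiplicative illumination field
(flat/lateral-gradient/corner, range [0.55, 1] by default), exponential
distance attenuation `τ^(−Δd/5)`, auto-exposure gain `0.5/mean-luminance`
clipped to [0.5, 2], white-balance gains, additive Gaussian sensor noise,
clipping, gamma encoding. Every corruption has an exact inverse in the
package in the noise-free limit, which is asserted as a closure property.
Renders are continuous-valued; 8-bit quantization happens only on PNG
write, so closure can be tested below the quantization floor.

The cohort generator draws Fitzpatrick strata (II–VI) with stratum
lightness means 66/60/53/45/36, melanin from a 4-parameter logistic link
to 1/L\* (A = 25, B = 100, x₀ = 0.021, s = 0.004) with reflectance
`10^(−M/100)`, gold SpO₂ from a cyanotic (N(82, 4), weight 8/26) /
noncyanotic (N(97, 1.2)) mixture, the oximeter index as
`F = A − 0.08·(M − 35) + ε` with ε ~ N(0, 0.2) — a melanin-proportional
underestimation — imaged tones as affine distortions of the standard tones
plus an ISO shift, and lip/pCO₂ features with independent components so
that generating weights are identifiable. The dye map is Beer–Lambert,
`channel = base·10^(−k·conc)`, with `k_G − k_R = 0.0013` chosen so the SCQP
signal is near-linear over 0–100 µg/mL (linear R² ≈ 0.998), the regime in
which saturation-derived quantification is reported to hold.

What passing tests on this simulator **do not** show: performance on real
lips (flat color patches, no texture, shape or specular physiology), real
optics (the attenuation model is exponential by construction), real camera
response (sRGB assumed exactly), or clinical accuracy (the generator's
noise scales are plausible, not measured). The simulator demonstrates that
the algorithms invert the interferences they model and recover parameters
they can identify — a necessary condition, not a clinical validation.

# Numerical choices and degenerate inputs

- Achromatic pixels: hue reported as 0 with an explicit flag; SCQP on
  achromatic black (V = 0) is a defined-value error.
- Evenness calibration on black pixels (V = 0): channels set to the
  equalized value (the only hue-free choice).
- Calibration with "no correction" parameters (μ = 1, ΔDistance = 0) is
  exactly the identity; idempotence is tested.
- Grey-world balancing errors on any zero-mean channel, and fixes channel
  ratios only — overall exposure is unconstrained, so comparisons normalize
  by the global mean.
- kmeans grid clustering uses quantile-initialized centers, making
  detection deterministic for a given image.
- All predictions are clipped to physical ranges: SpO₂ [0, 100] %, pCO₂
  [10, 100] mmHg.

# Problem sizes

The suite and the acceptance script run on desk-scale sizes chosen to keep
every statistical check well-powered: 10^4 random colors for the identity
and round-trip properties, 368 px chip frames under 2 illumination fields ×
2 distances, 200-subject cohorts for correction fits (10^3 for the
residual-independence check), 50–100-point oracle sets for the regression
comparisons, and 10^5 draws for the Bland–Altman Monte-Carlo.

# Known limitations

- The evenness correction is additive in V; a strongly multiplicative
  shading field over a high-contrast scene leaves a residual proportional
  to the local reflectance difference (visible as the raw-G pipeline's
  large errors; SCQP is immune by construction).
- Grid detection assumes one chip, near-axis-aligned, occupying most of the
  frame; perspective distortion is out of scope.
- The SVR and Lasso optimizers are subgradient methods: accuracy at a kink
  is limited by the learning-rate schedule; the defaults favour speed and
  the oracle configurations favour precision.
- The melanin index uses a single narrow band (655 nm); hemoglobin
  cross-absorption is not modeled.
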