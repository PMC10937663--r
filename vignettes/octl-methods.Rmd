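---
title: "Label-free OCT lymphangiography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free OCT lymphangiography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octlseg)
```

## The imaging problem

Lymphatic vessels and aqueous veins carry nearly transparent fluid (lymph,
aqueous humor). In an OCT scan they appear as regions of markedly *low*
backscatter inside bright scattering tissue — the opposite contrast of OCT
angiography, which relies on moving scatterers in blood. OCT
lymphangiography (OCTL) therefore reduces to segmenting low-signal tubular
structures in a 3-D log-intensity volume.

Two segmenters are implemented here:

1. **Conventional OCTL** — physics-based: correct the instrument's axial
   response, fit the single-scattering decay model per A-scan, compensate
   the attenuation so that homogeneous tissue becomes depth-constant, and
   apply one constant threshold to the whole compensated volume.
2. **DL-OCTL** — a U-Net trained, with Dice loss and Adam, on the labels
   produced by the conventional method. Once trained it needs no physics
   and, because it sees whole B-scans, it does not inherit the conventional
   method's modelling artifacts.

No scanner data ships with the package; a synthetic phantom generator
(`phantom_spec()`, `make_eye_phantom()`, `make_calibration_volume()`,
`make_raw_spectra()`) renders every input the pipeline needs, together with
geometric ground truth, so that each stage is testable end to end.

## Signal model

All volumes are stored as intensity dB, `10*log10(I)`, indexed `[x, y, z]`
with `z = 1` the shallowest sample. Depth is *optical path length*;
physical depth in tissue is optical depth divided by the refractive index
(default `n = 1.4`, appropriate near 1300 nm; `optical_to_physical()`).

The phantom renders the single-scattering model

\[ I(z) = I_0 \, H(z) \, e^{-2\mu z}, \]

with `z` physical depth below the local surface, attenuation coefficient
`mu` (mm^-1) and the combined axial system response `H(z)` — a
Lorentzian-like confocal factor `1/(1 + ((z - z_f)/z_R)^2)` times an
exponential sensitivity roll-off (dB linear in depth). In dB the model is a
straight line of slope `-2 mu * 10/ln 10` ≈ `-8.686 mu` dB per physical mm,
which is what the conventional fit estimates and what several unit tests
check in closed form.

**Speckle.** Intensity is multiplied by `1 + c (E - 1)` with `E ~ Exp(1)`
and contrast `c` in `[0, 1]`: `c = 1` is fully developed speckle, `c = 0`
noiseless. The additive noise floor (normalized to 0 dB by
`normalize_noise()`) is added in linear intensity before the dB conversion.
The default `c = 0.2` emulates the effective contrast of scans after the
spatial averaging/compounding that practical scanners apply; it is the
"clean scan" study condition used throughout the tests. Fully developed
speckle (`c = 1`) is exercised where the statistics matter — the
attenuation-fit recovery checks. What the default does *not* emulate:
correlated speckle grains, multiple scattering tails, motion, or
heterogeneous scatterer density; conclusions from passing tests therefore
concern the algorithmic pipeline, not scanner-grade robustness.

**Vessels.** Tubes are polyline centerlines with per-vertex radii;
irregular radius profiles emulate lymphatics, constant profiles aqueous
veins. Rendering subtracts a fixed dB deficit inside the tube; ground truth
is purely geometric (distance to centerline ≤ local radius), never
intensity-derived, so segmentation accuracy is measured against geometry.

**Superficial layer.** An optional band below the surface (default
thickness 50 µm, emulating a conjunctival epithelium) is rendered darker by
a configurable deficit. It breaks the depth-homogeneity assumption of the
single-scattering fit and is the artifact source studied in the
artifact-mitigation tests.

## Conventional OCTL: parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `mu_cal` | 0.1 | mm^-1 | attenuation of the calibration phantom; its decay is added back before re-zeroing `H` |
| `guard_px` | 5 | px | skip the specular surface peak before fitting |
| `noise_margin_db` | 3 | dB | fit window ends at the last sample this far above the floor |
| `min_window_px` | 20 | px | shorter windows are flagged invalid, not zeroed |
| `rel_db` | 8 | dB | default threshold = tissue mode − 8 dB on the compensated volume |
| `crop_um` | 500 | µm tissue | analysis band below the surface; deeper signal is unreliable |
| Canny `sigma`, `low`, `high` | 2, 0.1, 0.3 | px, fractions | surface edge detection per B-scan |
| median width | 15 | px | lateral smoothing of the surface map |

The threshold is *mode-relative* by default because an absolute empirical
threshold does not transfer across renders; an absolute `theta_db` override
exists. The fit uses ordinary least squares on dB versus physical depth —
the log-domain choice keeps the estimator linear and makes the noiseless
recovery exact (tested to 1e-6 relative). Under fully developed speckle the
per-A-scan dB offset `E[10 log10 E] ≈ -2.51` dB is depth-independent, so
the slope (hence `mu`) stays unbiased; the median over a few thousand
A-scans recovers `mu` within 10%.

Surface detection is Canny (Gaussian blur, Sobel, non-maximum suppression,
hysteresis on the per-scan gradient range) per B-scan, taking the
shallowest edge per A-scan, followed by a per-A-scan one-dimensional
refinement to the steepest depth rise near the Canny estimate. The
refinement exists because the 2-D blur biases the edge by a fraction of a
pixel along a tilted surface, which breaks the orientation-invariance
property (segmenting the volume and its x-y transpose must agree); a 1-D
per-A-scan operation is orientation-independent by construction. B-scans
whose detected "surface" does not separate dark from bright (≥ 5 dB
contrast) are flagged unreliable and interpolated from neighbors.

Flattening uses integer pixel shifts so binary masks stay binary; vacated
deep samples are zero/`FALSE`-padded.

## The U-Net and its training

Architecture (`unet_spec()`): 4 double-3x3-convolution encoder blocks with
widths 32/64/128/256 and 2x2 max pooling, a double-conv bottleneck at 1/16
resolution (256 channels), a symmetric decoder with 2x2 transposed
convolutions and skip concatenations, and a final 1x1 convolution onto 2
classes. ReLU follows every 3x3 convolution; there are no normalization
layers. Convolutions use size-preserving zero padding so outputs match the
input B-scan; inputs must be divisible by 16 (use `pad16()`, which
`unet_predict()` applies and undoes automatically). Because padding is
zero-based, predictions within ~the receptive field of the pad boundary
can differ marginally between pad amounts; the prediction contract is that
`unet_predict()` always pads to the next multiple of 16.

Inputs are 8-bit conversions of the dB B-scans (`to_uint8()`: linear map of
`[0, vmax]` to 0..255 with `vmax` the volume's 99.9th percentile, fixed
across the volume, rounding half away from zero), rescaled to `[0, 1]`.

Training (`unet_train()`): Dice loss (`eps = 1`) with softmax
probabilities, Adam at initial learning rate 1e-4, no augmentation, random
300/150/150-style split (`split_dataset()`). Per epoch the mean IOU of the
thresholded predictions is recorded as the accuracy for the training group
(pre-update forward passes) and the validation group; the returned model is
the one with the best validation accuracy.

Two training choices were genuinely open and are set as package defaults:

* **Batch size 1.** One Adam step per B-scan. With small synthetic training
  sets the extra step count (rather than a larger averaged batch) is what
  brings the Dice loss near zero within the ~100-epoch convergence horizon.
* **Foreground-prior initialization.** The final layer's vessel-logit bias
  starts at −2 (`build_unet(fg_bias =)`), i.e. an initial vessel
  probability of ~0.12. Vessels occupy a few percent of a B-scan; starting
  from a low foreground prior keeps the Dice denominator small and removes
  a long plateau in which the loss barely moves while the background
  probability deflates. This is standard practice for sparse-foreground
  Dice training.

Early stopping: training stops after `patience` consecutive epochs with
training mean IOU at or above `iou_target` (default 0.995); the epoch
budget (default 150, 100 in the scaled-down studies) is a hard cap.

## Problem sizes used in the shipped studies

The test-suite and acceptance studies run scaled-down analogs chosen as the
package's standard desk-scale conditions: phantoms of 96–128 × 16–64
A-scans × 320 depth pixels (5.6 µm optical axial pitch, 12 µm lateral, i.e.
~1.3 mm optical depth), tissue `mu` = 3 mm^-1, surface SNR 25 dB, vessel
radii 25–45 µm with 15–20 dB deficits; U-Net widths 8/16/32/64 at
128 × 128 B-scans, 32 training B-scans, up to 100 epochs. The default
`unet_spec()` keeps the full 32/64/128/256 architecture for real use; the
narrower widths in the studies preserve the architecture shape (4
downsamplings, doubling widths) at a fraction of the arithmetic.

## Numerical and degenerate-input choices

* dB convention: intensity dB = `10*log10(|A|^2)` everywhere; amplitude
  ratios double as 6.02 dB steps (tested via the reconstruction).
* Reconstruction (`reconstruct()`): background subtraction, linear
  interpolation onto a uniform wavenumber grid (endpoints clamped), Hann
  apodization by default (Hamming/none available), inverse FFT, positive
  half. The axial pitch follows from the sampled wavenumber span,
  `pi / (N dk)`.
* `iou()` of two empty masks is 1: two segmenters that both report "no
  vessels" agree perfectly. IOU summaries use the sample (n−1) standard
  deviation.
* Dice `eps = 1` makes empty-target losses finite and exactly 0 for a
  perfect binary match.
* Softmax ties (probability exactly 0.5) resolve to non-vessel.
* Attenuation fits with windows shorter than `min_window_px` yield `NA`
  with `valid = FALSE`; `compensate()` passes such A-scans through
  unchanged rather than guessing.
* Constant A-scans fit `mu = 0` with `r_squared = 1` (a zero-variance fit
  is vacuously perfect).
* TIFF volumes store samples on a 32-bit linear grid with an integer dB
  offset and power-of-two gain in the JSON sidecar; round trips are exact
  to ~5e-10 of the dynamic range (the R `tiff` package has no float sample
  format). Masks round-trip exactly as 8-bit 0/1.

## Known limitations

* The phantom is a rendering model, not a wave-optics simulation: no
  correlated speckle, no multiple scattering, no birefringence, no motion.
* Lymphatic versus aqueous-vein discrimination is out of scope (as in
  practice it is done manually from vessel morphology).
* The conventional threshold's absolute value is acquisition-dependent;
  only the mode-relative default is portable across renders.
* Training at desk scale uses narrow widths and tens of B-scans; absolute
  IOU figures from the synthetic studies do not transfer to scanner data —
  the tests establish correctness of the machinery and the *relative*
  claims (convergence, agreement between the two segmenters, artifact
  mitigation).
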