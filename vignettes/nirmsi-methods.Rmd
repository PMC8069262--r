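---
title: "OTN-NIR multispectral tumor discrimination: models, parameters and design choices"
author: "nirmsi authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OTN-NIR multispectral tumor discrimination: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nirmsi)
```

`nirmsi` analyses over-1000-nm near-infrared (OTN-NIR) multispectral image
cubes: 14 narrow bands between 1000 and 1400 nm recorded by a 12-bit
320 × 256 short-wave-infrared sensor, one reflectance spectrum per pixel.
This vignette documents the models the package implements, the parameters
that matter, the synthetic phantom that stands in for animal data, and the
design decisions taken where conventions were genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Absorbance calibration

Counts are converted to absorbance per pixel and band,

$$A = -\log_{10}\frac{I_r - I_d}{I_w - I_d},$$

with $I_r$, $I_w$, $I_d$ the raw, white-standard and dark counts. Two
degenerate cases need rules:

* **Non-positive denominator.** When $I_w - I_d \le 0$ at *any* band the
  whole pixel is excluded — marked invalid and NaN across its spectrum.
  Equality is included because division by zero is as undefined as a
  negative reflectance, and the exclusion is per spectrum rather than per
  pixel-band because the spectrum is the downstream unit of analysis: a
  pixel with one unusable band cannot enter SNV or the classifier anyway.
* **Non-positive numerator.** $I_r - I_d \le 0$ can happen under noise in
  deep shadow. These pixels are *clamped* to a small positive epsilon
  (default 0.5 count, configurable), capping the absorbance instead of
  discarding the pixel: shadowed pixels are a real feature of unevenly
  illuminated scenes and should stay in the map.

Exposure follows the convention that the white standard peaks near 90% of
the 4095-count dynamic range; `checkExposure()` flags bands whose fill
fraction leaves [0.80, 0.98] (the window is a package choice around the
90% target) and any saturated band.

Invalid pixels propagate: once invalid, a pixel is NaN in every cube,
absent from every dataset, and NaN/unscored in every probability map.

## Band registration

Changing the band changes the optical power and hence the angle of view by
a few pixels; all bands are realigned to the widest-field 1000 nm band.
The transform is deliberately restricted to uniform scale about the image
center plus translation (3 degrees of freedom, bilinear interpolation by
default) — the physical drift is a magnification change, and a full 6-dof
affine would only add estimation variance. Order of operations: raw,
white and dark cubes are registered first, then calibrated, because the
absorbance ratio requires corresponding pixels.

`estimateRegistration()` recovers the parameters by maximizing normalized
cross-correlation against the reference band: a coarse scale grid
(default ±5% in 0.5% steps) followed by Nelder-Mead refinement of
(scale, tx, ty). Both images are pre-smoothed with a 1-px Gaussian before
correlating; without this, interpolation smooths sensor noise by a
scale-dependent amount and biases the NCC maximizer by a few tenths of a
percent in scale. With it, recovery on default-scale phantoms is about an
order of magnitude inside the ±0.2% scale / 0.3 px acceptance window.
How the original system's parameters were obtained is not recorded
anywhere; this estimator is the package's own reconstruction and is
validated only on phantoms.

## SNV and dataset assembly

The standard normal variate transform $Z(x) = (x - \bar x)/s_x$ removes
additive baselines and multiplicative scatter per spectrum. The SD
convention is the *sample* SD ($n-1$), the prevailing chemometrics choice;
population SD is available (`sdType = "population"`) for sensitivity
checks and differs only by the factor $\sqrt{n/(n-1)}$. Constant spectra
have no SNV transform: they raise an error scalar-wise, and pixel-wise
they are flagged degenerate and left unscored rather than classified.

`buildDataset()` takes one row per labeled valid pixel — normal teaching
rows from pre-implantation images, tumor rows from expert-style tumor
masks of post-implantation images — and sorts rows by (animal, row, col)
so assembly is order-deterministic. Unlabeled pixels never train, but are
classified at prediction time.

## The classifier

A dense multilayer perceptron written from its defining equations:
$z_j = \sum_i w_{ij} x_i + b_j$ per unit, ReLU ($\max(0, z)$) or sigmoid
hidden activations, a single sigmoid output unit emitting the tumor
probability, binary cross-entropy loss (the standard pairing with a
sigmoid probability output), backpropagation gradients, Adam updates with
bias-corrected moments, and inverted dropout on every layer's output
except the final layer, so evaluation needs no rescaling. An `identity`
hidden activation exists for diagnostics — it makes the dropout
expectation exactly enumerable, which the test suite exploits.

The original network's architecture and hyperparameters are not printed
anywhere, so all of these are configuration with package-chosen defaults:

| parameter | default | notes |
|---|---|---|
| hidden layers | 64–32 | desk-scale; any sizes accepted |
| learning rate | 1e-3 | Adam, betas (0.9, 0.999), eps 1e-8 |
| batch size | 256 | |
| epochs | 100 | |
| dropout | 0.5 | training mode only, all layers except final |
| class weighting | none | mirrors the natural ~20:1 normal:tumor imbalance |
| cutoff | 0.60 | $p \ge 0.60$ counts as tumor (boundary inclusive) |

Results that depend on these are checked property-wise (separability,
monotone degradation), never value-matched. Two numerical notes: the
gradient of sigmoid-plus-BCE is computed as $(p - y)$ directly (no clamped
logs in the gradient path), and all randomness — initialization, shuffling,
dropout — flows from seeds derived by a stable string hash
(`deriveSeed()`), so a (data, config, seed) triple reproduces weights
bit-for-bit.

## Cross-validation and metrics

The unit of cross-validation is the **animal**: each animal's
post-implantation map is predicted by a model trained on the other
animals' datasets only. Pixel-level CV would leak spectra between
training and test and is rejected by construction; a test corrupts the
held-out animal's labels and asserts its prediction is unchanged. Each
fold gets an independent initialization seeded from
`deriveSeed(seed, "fold", heldOutId)`; whether the original analysis
shared initializations across folds is unknown, and independent seeds are
the safer default.

Specificity, sensitivity and accuracy are percentages of the pooled
confusion counts; the "total" row is always recomputed from *summed
counts*, never by averaging per-animal percentages (the two differ
whenever class sizes vary — a test constructs the counterexample).
Display rounds to one decimal; full precision is retained in the JSON
twin of every report.

## The phantom generator

The generator emulates the acquisition the pipeline expects, with exact
ground truth:

* Geometry: an elliptical body on a dim background, plus one elliptical
  tumor after "implantation"; per-animal jitter in position and size.
  Default cohort: 9 animals, imaged pre- and post-implantation.
* Spectra: smooth water-like normal-tissue absorbance rising toward
  1400 nm; the tumor endmember is depressed by Gaussian bumps centered at
  the delta bands (default 1070, 1250, 1400 nm). The bump depth is
  `tumorContrast × noiseSd` (relative reflectance), so class separation is
  expressed directly in noise-SD units; no absolute effect size is
  published anywhere, so the effect size is a free, configurable
  parameter.
* Sensor: composition `raw = dark + R · (white − dark)` under a smooth
  vignetted illumination shared bit-for-bit by the white cube; 1%
  multiplicative noise; dark offset 100 counts; white exposure at 90% of
  4095 (white-frame noise is reduced 0.3×, standing in for the frame
  averaging a real white acquisition would use, and keeping the per-band
  peak within the ±2% exposure contract); 12-bit quantization.
* Nuisances: per-band magnification drift up to 2% (the 1000 nm band is
  the widest, matching the registration convention), optional saturated
  halation and near-dark shadow patches (10% probability each).
* Labels are conservative by design: the tumor label is eroded ~1.5 px
  inside the true ellipse and the normal label is a strip of the back
  kept clear of the tumor — emulating expert ROIs that avoid ambiguous
  boundary pixels, and making scored pixels robust to the ~0.5 px edge
  mixing that drift resampling introduces.

With noise, drift and artifacts all zero (and `quantize = FALSE`) the
phantom is analytic: calibrated absorbance equals
$-\log_{10}(\text{endmember})$ to machine precision, which the suite
checks at 1e-12.

What the phantom does **not** model: anatomy, tissue scattering and
partial-volume spectra, breathing/heartbeat motion blur, hair-follicle
skin structure, inter-animal spectral variability. Passing the recovery
tests therefore demonstrates that the *pipeline* is correct and sensitive
at a known effect size — not that any particular in vivo sensitivity is
reproducible; real-tissue performance is limited by exactly the features
the phantom omits.

## Problem sizes and the recovery runs

The phantom-recovery cross-validation runs use 9 animals at 96 × 120 px,
14 bands, tumor semi-axes 8–12 px (≈ 150–400 labeled tumor px and ≈ 2,000
labeled normal px per animal) — large enough for stable pooled rates,
small enough that the full double (strong + weak) LOOCV finishes in a few
minutes on one core. The training schedule for these runs (120 epochs,
batch 256, learning rate 3e-3, dropout 0) was chosen on convergence
diagnostics: per-fold loss plateaus smoothly there, whereas more
aggressive rates oscillate between good and poor final iterates, and
dropout on 14 strongly correlated input bands removes the discriminative
bands often enough to stall learning at the majority-class plateau.
Dropout remains the default for real-data use, where regularization
against inter-animal variability is the point; the recovery run measures
the pipeline, not generalization under biological variability, and says
so here rather than pretending the choice is neutral.

At the strong setting (class separation 3× noise SD at the delta bands)
the pooled leave-one-animal-out accuracy and sensitivity sit in the high
90s; reducing the separation to 0.5× noise SD collapses sensitivity
toward zero while specificity stays high — the monotonicity of difficulty
the design predicts, and the same low-sensitivity/high-specificity regime
the natural class imbalance produces in practice. The exact values for a
given seed are written by `scripts/acceptance.R`.

## Known limitations

* The registration model is scale + translation only; rotation or shear
  in a real instrument would require extending `BandRegistration`.
* `estimateRegistration` needs shared structure across bands; featureless
  bands error out by design.
* The MLP is plain R matrix arithmetic — fine at desk scale (tens of
  thousands of pixels, tens of epochs), not tuned for hundreds of
  megapixel-scale cubes.
* The phantom's artifact model (hard saturation discs, uniform-attenuation
  shadows) is deliberately crude; artifacts exercise the exclusion and
  degeneracy paths, nothing more.
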