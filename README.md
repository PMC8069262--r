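# nirmsi

Pixel-wise tumor discrimination from over-1000-nm near-infrared (OTN-NIR)
multispectral image cubes.

## The problem

Short-wave infrared light in the 1000–1400 nm "second biological window"
penetrates millimeters of tissue and carries overtone/combination-band
chemical contrast that RGB imaging cannot see. A multispectral camera
records a 14-band spectrum at every pixel of a 320 × 256, 12-bit frame;
the question is whether those per-pixel spectra separate subcutaneous
tumor tissue from normal tissue in vivo. `nirmsi` implements the complete
analysis chain for such data, for imaging scientists who want a tested,
reproducible reference pipeline:

1. **Absorbance calibration.** With raw, white-standard and dark-frame
   counts `Ir`, `Iw`, `Id` at each pixel,
   `A = -log10((Ir - Id) / (Iw - Id))`; pixels with `Iw - Id <= 0` at any
   band are excluded (NaN across the spectrum). Exposure is checked
   against the convention that the white standard peaks near 90% of the
   4095-count dynamic range.
2. **Band registration.** The angle of view drifts by a few pixels with
   wavelength; every band is realigned to the widest-field 1000 nm band by
   a scale-about-center + translation transform, either supplied or
   estimated by normalized cross-correlation with sub-pixel refinement.
3. **SNV normalization.** Each pixel's absorbance spectrum `x` becomes
   `Z(x) = (x - mean(x)) / sd(x)`, removing additive baselines and
   multiplicative scatter.
4. **Neural-network classification.** A dense multilayer perceptron
   (`z_j = sum_i w_ij x_i + b_j`, ReLU/sigmoid activations, sigmoid output)
   is written from its defining equations: backpropagation gradients of
   binary cross-entropy, inverted dropout on every layer except the final
   one, Adam updates. The output is the per-pixel tumor probability,
   rendered as a heatmap and binarized at a 60% cutoff.
5. **Leave-one-animal-out cross-validation.** Each animal's pixels are
   scored by a model trained on the other animals only;
   specificity = TN/(FP+TN), sensitivity = TP/(TP+FN),
   accuracy = (TP+TN)/total are reported per animal and pooled from summed
   counts.
6. **Optics QC.** Michelson contrast `(Imax - Imin)/(Imax + Imin)` of
   three-bar resolution elements, with the Rayleigh call (resolved when
   contrast > 0.26).

Because no public dataset of this kind exists, the package ships a
synthetic phantom-cohort generator (`phantomSpec()`, `generateCohort()`)
with exact ground truth — tissue reflectance endmembers that diverge near
1070, 1250 and 1400 nm, sensor dark offset and noise, 90%-fill white
references, band-dependent magnification drift, halation/shadow artifacts
— so every stage is testable end to end.

## Worked example

```r
library(nirmsi)

spec <- phantomSpec(height = 96L, width = 120L, nAnimals = 9L,
                    tumorRadiusPx = c(8, 12), tumorContrast = 3, seed = 101L)
cohort <- generateCohort(spec)
cfg <- trainConfig(epochs = 120L, batchSize = 256L, learningRate = 3e-3,
                   dropoutRate = 0, seed = 7L)
res <- runLOOCV(cohort, layerSizes = c(32L, 16L), config = cfg)
res$reports[res$reports$animal_id == "total",
            c("tumor_px", "normal_px", "specificity_pct",
              "sensitivity_pct", "accuracy_pct")]
#>    tumor_px normal_px specificity_pct sensitivity_pct accuracy_pct
#> 10     2208     19040        99.72164        95.92391       99.327
```

Read: of 2,208 tumor-labeled and 19,040 normal-labeled pixels scored
across the nine held-out animals, 95.9% of tumor pixels and 99.7% of
normal pixels were classified correctly by models that never saw the
scored animal — the phantom's 3-noise-SD spectral separation is recovered
through the full calibrate → register → SNV → train → predict chain.
The published-count reproduction is immediate:

```r
classificationMetrics(c(TP = 2629, FN = 2287, FP = 10212, TN = 87292))
#>   animal_id tumor_px normal_px specificity_pct sensitivity_pct accuracy_pct ...
#> 1     total     4916     97504        89.52658        53.47844     87.79633
```

which rounds to the familiar 89.5 / 53.5 / 87.8.

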