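Package: nirmsi
Title: Over-1000-nm Near-Infrared Multispectral Imaging Analysis for Pixel-Wise Tumor Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for over-1000-nm near-infrared (OTN-NIR)
    multispectral image cubes of tumor-bearing animals: dark/white-reference
    absorbance calibration with pixel exclusion, band-to-band affine
    registration against the widest-field wavelength, standard normal variate
    (SNV) spectral normalization, a from-equations dense neural network
    trained by backpropagation with dropout and Adam for per-pixel tumor
    probability maps, leave-one-animal-out cross-validation with
    specificity/sensitivity/accuracy reporting, Michelson-contrast resolution
    analysis of bar targets, and a synthetic phantom-cohort generator with
    known ground truth that exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tiff, jsonlite, yaml, png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'io.R'
    'phantom.R'
    'calibration.R'
    'registration.R'
    'preprocessing.R'
    'mlp.R'
    'evaluation.R'
    'opticsQC.R'
    'pipeline.R'
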