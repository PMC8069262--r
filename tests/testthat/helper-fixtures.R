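# Small phantom specifications used across the suite; frame sizes are kept
# desk-scale so fixtures regenerate in milliseconds.

tinySpec <- function(..., nAnimals = 2L, seed = 42L) {
  phantomSpec(height = 48L, width = 64L, nAnimals = nAnimals,
              tumorRadiusPx = c(5, 7), seed = seed, ...)
}

cleanSpec <- function(..., seed = 42L) {
  # analytic phantom: no noise, no drift, no artifacts, no quantization
  tinySpec(noiseSd = 0, bandScaleDrift = 0, halationProb = 0, shadowProb = 0,
           quantize = FALSE, seed = seed, ...)
}

# A flat counts cube of the given per-band values.
flatCube <- function(vals, H = 4L, W = 5L, wl = seq(1000, by = 50,
                                                    length.out = length(vals))) {
  v <- array(rep(vals, each = H * W), c(H, W, length(vals)))
  spectralCube(v, wl)
}

# Smooth scene builder for resampling fixtures (smoothness only; not an oracle).
gaussianBlurRef <- function(m, sigma) nirmsi:::gaussianBlur(m, sigma)

# Absorbance cube with fully controllable values (valid everywhere).
absCube <- function(v, wl = seq(1000, by = 50, length.out = dim(v)[3])) {
  spectralCube(v, wl, space = "absorbance")
}
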