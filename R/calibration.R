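#' @include AllClasses.R
NULL

#' Convert a raw/white/dark bundle to absorbance
#'
#' Per pixel and band, absorbance A = -log10((Ir - Id) / (Iw - Id)) where
#' Ir, Iw, Id are the raw, white-standard and dark counts.  Any pixel whose
#' white-minus-dark difference is <= 0 at any band is excluded: marked
#' invalid and set NaN across its whole spectrum (the pixel's spectrum is
#' the unit of analysis).  A non-positive numerator (possible under noise
#' in dark shadows) is clamped to a small positive epsilon instead, capping
#' the absorbance but keeping the pixel in the map.
#'
#' @param bundle a \linkS4class{CubeBundle} with counts cubes.
#' @param epsilon clamp floor for the numerator, in counts (default 0.5).
#' @return a \linkS4class{SpectralCube} in absorbance space; its validity
#'   mask is the conjunction of the input masks and the exclusion rule.
#' @examples
#' wl <- c(1000, 1200)
#' mk <- function(v) spectralCube(array(v, c(2, 2, 2)), wl)
#' a <- computeAbsorbance(cubeBundle(mk(368), mk(3686), mk(0)))
#' cubeValues(a)[1, 1, 1]  # one decade below the white standard: A = 1
#' @export
computeAbsorbance <- function(bundle, epsilon = 0.5) {
  raw <- bundle@raw; white <- bundle@white; dark <- bundle@dark
  if (cubeSpace(raw) != "counts" || cubeSpace(white) != "counts" ||
      cubeSpace(dark) != "counts")
    stop("absorbance calibration requires counts cubes")
  d <- dim(raw@values)
  denom <- white@values - dark@values
  numer <- raw@values - dark@values
  excluded <- apply(denom <= 0, c(1, 2), any)
  valid <- raw@valid & white@valid & dark@valid & !excluded
  numer[numer <= 0] <- epsilon
  A <- -log10(numer / denom)
  A[array(!valid, dim = d)] <- NaN
  spectralCube(A, raw@wavelengths, bitDepth = raw@bitDepth, valid = valid,
               space = "absorbance")
}

#' Check white-reference exposure per band
#'
#' The exposure convention sets the white standard's per-band maximum near
#' 90% of the 12-bit dynamic range (about 3686 of 4095); a band passes when
#' its fill fraction lies in [lo, hi] and is flagged saturated when any
#' count reaches the ceiling.
#'
#' @param white a counts \linkS4class{SpectralCube} of the white standard.
#' @param lo,hi acceptable fill-fraction window (defaults 0.80, 0.98).
#' @return data.frame: band, wavelength_nm, max_count, fill_fraction,
#'   pass, saturated.
#' @export
checkExposure <- function(white, lo = 0.80, hi = 0.98) {
  if (cubeSpace(white) != "counts") stop("exposure check requires a counts cube")
  mx <- 2^white@bitDepth - 1
  B <- nBands(white)
  maxc <- vapply(seq_len(B), function(b) max(white@values[, , b]), 0)
  fill <- maxc / mx
  data.frame(band = seq_len(B), wavelength_nm = white@wavelengths,
             max_count = maxc, fill_fraction = fill,
             pass = fill >= lo & fill <= hi, saturated = maxc >= mx)
}
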