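#' @include AllClasses.R
NULL

#' Pixel values of a cube or map
#' @param x object.
#' @param ... unused.
#' @export
setGeneric("cubeValues", function(x, ...) standardGeneric("cubeValues"))

#' Wavelength axis in nm
#' @param x object.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Number of spectral bands
#' @param x object.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Per-pixel validity mask
#' @param x object.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Value space of a cube ("counts" or "absorbance")
#' @param x object.
#' @export
setGeneric("cubeSpace", function(x) standardGeneric("cubeSpace"))
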