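#' @include AllGenerics.R
NULL

#' @describeIn SpectralCube the H x W x B value array.
#' @param x,object a \code{SpectralCube}.
#' @param ... unused.
#' @export
setMethod("cubeValues", "SpectralCube", function(x, ...) x@values)

#' @describeIn SpectralCube the wavelength axis (nm).
#' @export
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)

#' @describeIn SpectralCube the band count.
#' @export
setMethod("nBands", "SpectralCube", function(x) dim(x@values)[3])

#' @describeIn SpectralCube the per-pixel validity mask.
#' @export
setMethod("validMask", "SpectralCube", function(x) x@valid)

#' @describeIn SpectralCube the value space.
#' @export
setMethod("cubeSpace", "SpectralCube", function(x) x@space)

#' @describeIn SpectralCube dimensions (H, W, B).
#' @export
setMethod("dim", "SpectralCube", function(x) dim(x@values))

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralCube: %d x %d px, %d band(s) [%g..%g nm], %s (%d-bit)\n",
              d[1], d[2], d[3], min(object@wavelengths), max(object@wavelengths),
              object@space, object@bitDepth))
  nin <- sum(!object@valid)
  if (nin > 0) cat(sprintf("  %d invalid pixel(s)\n", nin))
})

#' @describeIn ProbabilityMap the probability values.
#' @param x a \code{ProbabilityMap}.
#' @param ... unused.
#' @export
setMethod("cubeValues", "ProbabilityMap", function(x, ...) x@values)

setMethod("show", "CubeBundle", function(object) {
  d <- dim(object@raw@values)
  cat(sprintf("CubeBundle '%s' (%s): %d x %d px, %d bands\n",
              object@animalId, object@session, d[1], d[2], d[3]))
  if (!is.null(object@labels))
    cat(sprintf("  labels: %d normal, %d tumor px\n",
                sum(object@labels == 1L), sum(object@labels == 2L)))
})

setMethod("show", "BandRegistration", function(object) {
  cat(sprintf("BandRegistration: %d bands, reference band %d, %s\n",
              length(object@scale), object@referenceBand, object@interpolation))
  cat(sprintf("  scale %.4f..%.4f, |t| <= %.2f px\n", min(object@scale),
              max(object@scale), max(abs(c(object@tx, object@ty)))))
})

setMethod("show", "PixelDataset", function(object) {
  cat(sprintf("PixelDataset: %d pixels x %d bands (%d normal, %d tumor), %d animal(s)\n",
              nrow(object@X), ncol(object@X), sum(object@y == 0L),
              sum(object@y == 1L), length(unique(object@animalId))))
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf("MLPModel: %s, hidden %s, output sigmoid, dropout %.2f\n",
              paste(object@layerSizes, collapse = "-"),
              object@hiddenActivation, object@dropoutRate))
})

setMethod("show", "ProbabilityMap", function(object) {
  v <- object@values
  cat(sprintf("ProbabilityMap: %d x %d px, cutoff %.2f, %d unscored px\n",
              nrow(v), ncol(v), object@cutoff, sum(is.na(v))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %d animals, %d x %d px, %d bands ",
                     "[%g..%g nm]\n  noise %.3f, drift %.3f, white fill %.2f, seed %d\n"),
              object@nAnimals, object@height, object@width,
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths), object@noiseSd, object@bandScaleDrift,
              object@whiteFill, object@seed))
})

#' Number of rows (pixels) in a dataset
#' @param x a \code{PixelDataset}.
#' @export
setMethod("length", "PixelDataset", function(x) nrow(x@X))

#' Extract the feature matrix and labels of a dataset
#' @param dataset a \linkS4class{PixelDataset}.
#' @return list with X, y, animalId, pixelIndex, wavelengths.
#' @export
datasetMatrix <- function(dataset) {
  list(X = dataset@X, y = dataset@y, animalId = dataset@animalId,
       pixelIndex = dataset@pixelIndex, wavelengths = dataset@wavelengths)
}
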