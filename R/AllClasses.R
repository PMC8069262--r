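#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' SpectralCube: a multi-band image cube
#'
#' The central image container: an H x W x B array of per-pixel intensities
#' (sensor counts) or absorbances, together with its ascending wavelength
#' axis, the sensor bit depth, a per-pixel validity mask, and the value
#' space.  Invalid pixels of absorbance cubes carry NaN across all bands;
#' counts cubes never carry NaN.
#'
#' @slot values numeric H x W x B array.
#' @slot wavelengths numeric, length B, strictly increasing, in nm.
#' @slot bitDepth integer; 12 for the native sensor (counts in 0..4095).
#' @slot valid logical H x W mask; FALSE where the calibration exclusion or
#'   resampling out-of-frame applied.
#' @slot space "counts" or "absorbance".
#' @export
setClass("SpectralCube",
  representation(values = "array", wavelengths = "numeric",
                 bitDepth = "integer", valid = "matrix", space = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3) return("values must be a 3-d (H x W x B) array")
    if (length(object@wavelengths) != d[3])
      return("wavelength count must equal band count")
    if (d[3] > 1 && any(diff(object@wavelengths) <= 0))
      return("wavelengths must be strictly increasing")
    if (!identical(dim(object@valid), d[1:2]))
      return("valid mask dimensions must match the image plane")
    if (!is.logical(object@valid)) return("valid mask must be logical")
    if (!object@space %in% c("counts", "absorbance"))
      return("space must be 'counts' or 'absorbance'")
    if (object@space == "counts") {
      if (anyNA(object@values)) return("counts cubes must not contain NA/NaN")
      mx <- 2^object@bitDepth - 1
      if (min(object@values) < 0 || max(object@values) > mx)
        return(sprintf("counts must lie in [0, %d]", mx))
    } else {
      bad <- array(!object@valid, dim = d)  # recycled across bands
      if (any(bad) && !all(is.na(object@values[bad])))
        return("invalid pixels of an absorbance cube must be NaN at all bands")
    }
    TRUE
  })

#' Construct a SpectralCube
#'
#' @param values H x W x B numeric array (a matrix is promoted to B = 1).
#' @param wavelengths ascending wavelengths in nm, one per band.
#' @param bitDepth sensor bit depth (default 12, i.e. counts 0..4095).
#' @param valid optional H x W logical mask (default all TRUE).
#' @param space "counts" (default) or "absorbance".
#' @return a \linkS4class{SpectralCube}.
#' @examples
#' cube <- spectralCube(array(100, c(4, 5, 2)), c(1000, 1400))
#' nBands(cube)
#' @export
spectralCube <- function(values, wavelengths, bitDepth = 12L, valid = NULL,
                         space = c("counts", "absorbance")) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  space <- match.arg(space)
  if (is.null(valid)) valid <- matrix(TRUE, dim(values)[1], dim(values)[2])
  new("SpectralCube", values = values, wavelengths = as.numeric(wavelengths),
      bitDepth = as.integer(bitDepth), valid = valid, space = space)
}

#' CubeBundle: raw / white-reference / dark triplet for one acquisition
#'
#' Groups the three cubes the absorbance calibration needs — the raw scene,
#' the white diffuse-reflectance standard, and the dark frame — plus an
#' optional label mask (0 = unlabeled, 1 = normal, 2 = tumor), the animal id
#' and the imaging session.
#'
#' @slot raw,white,dark \linkS4class{SpectralCube}s sharing shape and
#'   wavelength axis.
#' @slot labels integer H x W matrix in {0,1,2}, or NULL.
#' @slot animalId character scalar.
#' @slot session "pre_implant" or "post_implant".
#' @export
setClass("CubeBundle",
  representation(raw = "SpectralCube", white = "SpectralCube",
                 dark = "SpectralCube", labels = "matrixOrNULL",
                 animalId = "character", session = "character"),
  validity = function(object) {
    d <- dim(object@raw@values)
    if (!identical(d, dim(object@white@values)) ||
        !identical(d, dim(object@dark@values)))
      return("raw, white and dark cubes must share height, width and bands")
    if (!isTRUE(all.equal(object@raw@wavelengths, object@white@wavelengths)) ||
        !isTRUE(all.equal(object@raw@wavelengths, object@dark@wavelengths)))
      return("raw, white and dark wavelength axes must be identical")
    if (!object@session %in% c("pre_implant", "post_implant"))
      return("session must be 'pre_implant' or 'post_implant'")
    if (!is.null(object@labels)) {
      if (!identical(dim(object@labels), d[1:2]))
        return("label mask dimensions must match the cubes")
      if (!all(object@labels %in% 0:2))
        return("labels must be 0 (unlabeled), 1 (normal) or 2 (tumor)")
    }
    TRUE
  })

#' Construct a CubeBundle
#'
#' @param raw,white,dark aligned counts \linkS4class{SpectralCube}s.
#' @param labels optional integer label mask (0/1/2).
#' @param animalId animal identifier.
#' @param session "pre_implant" or "post_implant".
#' @export
cubeBundle <- function(raw, white, dark, labels = NULL, animalId = "animal",
                       session = c("pre_implant", "post_implant")) {
  session <- match.arg(session)
  if (!is.null(labels)) storage.mode(labels) <- "integer"
  new("CubeBundle", raw = raw, white = white, dark = dark, labels = labels,
      animalId = animalId, session = session)
}

#' BandRegistration: per-band scale + translation correction
#'
#' Correction aligning every band to the reference-band geometry (the
#' 1000 nm band, whose angle of view is widest): a uniform scale about the
#' image center followed by a translation, applied per band.  The reference
#' band always carries the identity (scale 1, zero shift).
#'
#' @slot referenceBand 1-based index of the reference band.
#' @slot scale,tx,ty numeric vectors, one entry per band (tx along columns,
#'   ty along rows, in pixels).
#' @slot interpolation "bilinear" or "nearest".
#' @export
setClass("BandRegistration",
  representation(referenceBand = "integer", scale = "numeric",
                 tx = "numeric", ty = "numeric", interpolation = "character"),
  validity = function(object) {
    B <- length(object@scale)
    if (length(object@tx) != B || length(object@ty) != B)
      return("scale, tx, ty must have one entry per band")
    if (object@referenceBand < 1 || object@referenceBand > B)
      return("referenceBand out of range")
    if (any(object@scale <= 0)) return("scales must be > 0")
    r <- object@referenceBand
    if (object@scale[r] != 1 || object@tx[r] != 0 || object@ty[r] != 0)
      return("reference band must carry the identity transform")
    if (!object@interpolation %in% c("bilinear", "nearest"))
      return("interpolation must be 'bilinear' or 'nearest'")
    TRUE
  })

#' Construct a BandRegistration
#'
#' @param scale,tx,ty per-band affine parameters (recycled if scalar).
#' @param referenceBand reference band index (default 1, the shortest
#'   wavelength).
#' @param interpolation resampling kernel.
#' @param nBands number of bands when all parameters are scalar.
#' @export
bandRegistration <- function(scale = 1, tx = 0, ty = 0, referenceBand = 1L,
                             interpolation = c("bilinear", "nearest"),
                             nBands = max(length(scale), length(tx), length(ty))) {
  interpolation <- match.arg(interpolation)
  new("BandRegistration", referenceBand = as.integer(referenceBand),
      scale = rep_len(as.numeric(scale), nBands),
      tx = rep_len(as.numeric(tx), nBands),
      ty = rep_len(as.numeric(ty), nBands),
      interpolation = interpolation)
}

#' Identity registration for a cube
#' @param cube a \linkS4class{SpectralCube} (or a band count).
#' @param ... passed to \code{bandRegistration}.
#' @export
identityRegistration <- function(cube, ...) {
  B <- if (is(cube, "SpectralCube")) nBands(cube) else as.integer(cube)
  bandRegistration(scale = rep(1, B), tx = rep(0, B), ty = rep(0, B), ...)
}

#' PixelDataset: SNV spectra with labels, the learning substrate
#'
#' One row per labeled valid pixel; each row is the SNV-normalized
#' absorbance spectrum of that pixel (mean 0, unit sample SD by
#' construction).  Rows are sorted by (animalId, row, col) so dataset
#' assembly is order-deterministic.
#'
#' @slot X numeric N x B matrix of SNV spectra.
#' @slot y integer labels, 0 = normal, 1 = tumor.
#' @slot animalId character, length N.
#' @slot pixelIndex integer N x 2 matrix of 0-based (row, col) indices.
#' @slot wavelengths numeric length B.
#' @export
setClass("PixelDataset",
  representation(X = "matrix", y = "integer", animalId = "character",
                 pixelIndex = "matrix", wavelengths = "numeric"),
  validity = function(object) {
    n <- nrow(object@X)
    if (length(object@y) != n || length(object@animalId) != n ||
        nrow(object@pixelIndex) != n)
      return("X, y, animalId and pixelIndex must agree in length")
    if (ncol(object@X) != length(object@wavelengths))
      return("X column count must equal wavelength count")
    if (!all(object@y %in% 0:1)) return("labels must be 0 (normal) or 1 (tumor)")
    if (anyNA(object@X)) return("dataset rows must be NaN-free")
    if (n > 0) {
      mu <- rowMeans(object@X)
      if (max(abs(mu)) > 1e-8) return("rows must be SNV-centered (mean 0)")
    }
    TRUE
  })

#' MLPModel: dense neural network weights and configuration
#'
#' A fully connected network mapping a B-band SNV spectrum to a tumor
#' probability: per layer an affine map z = W'a + b followed by the
#' activation (ReLU or sigmoid hidden layers; sigmoid output, one unit).
#'
#' @slot layerSizes integer, input size through hidden sizes to 1.
#' @slot weights list of matrices, weights[[l]] is n_{l-1} x n_l.
#' @slot biases list of numeric vectors.
#' @slot hiddenActivation "relu", "sigmoid" or "identity" (diagnostic).
#' @slot dropoutRate dropout probability applied in training mode to every
#'   layer's output except the final layer (inverted-dropout scaling).
#' @slot seed integer seed used for initialization.
#' @export
setClass("MLPModel",
  representation(layerSizes = "integer", weights = "list", biases = "list",
                 hiddenActivation = "character", dropoutRate = "numeric",
                 seed = "integer"),
  validity = function(object) {
    L <- length(object@layerSizes)
    if (L < 2) return("need at least input and output layers")
    if (object@layerSizes[L] != 1L) return("output layer must have exactly 1 unit")
    if (length(object@weights) != L - 1 || length(object@biases) != L - 1)
      return("need one weight matrix and bias vector per layer transition")
    for (l in seq_len(L - 1)) {
      if (!identical(dim(object@weights[[l]]),
                     c(object@layerSizes[l], object@layerSizes[l + 1])))
        return(sprintf("weight matrix %d has inconsistent shape", l))
      if (length(object@biases[[l]]) != object@layerSizes[l + 1])
        return(sprintf("bias vector %d has inconsistent length", l))
    }
    if (!object@hiddenActivation %in% c("relu", "sigmoid", "identity"))
      return("hiddenActivation must be 'relu', 'sigmoid' or 'identity'")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      return("dropoutRate must lie in [0, 1)")
    TRUE
  })

#' ProbabilityMap: per-pixel tumor probability
#'
#' Output of the pixel classifier over a whole image: probability of the
#' tumor class in [0,1], NaN exactly where the source pixel was invalid or
#' its spectrum degenerate (constant, so SNV undefined).
#'
#' @slot values numeric H x W matrix in [0,1] or NaN.
#' @slot cutoff binarization threshold (default 0.60).
#' @export
setClass("ProbabilityMap",
  representation(values = "matrix", cutoff = "numeric"),
  validity = function(object) {
    v <- object@values[!is.na(object@values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      return("probabilities must lie in [0,1]")
    if (object@cutoff <= 0 || object@cutoff >= 1)
      return("cutoff must lie in (0,1)")
    TRUE
  })

#' PhantomSpec: parameters of the synthetic cohort generator
#'
#' Describes the emulated acquisition: frame geometry, the 14-band
#' wavelength axis, cohort size, tumor geometry, tissue reflectance
#' endmembers whose spectra diverge at the delta bands, sensor dark level
#' and noise, white-reference exposure as a fraction of the 12-bit dynamic
#' range, band-dependent magnification drift, and artifact probabilities.
#'
#' @slot height,width frame size in pixels.
#' @slot wavelengths band centers in nm.
#' @slot nAnimals cohort size.
#' @slot tumorRadiusPx min/max tumor semi-axis in pixels.
#' @slot endmemberNormal,endmemberTumor per-band reflectance in (0,1].
#' @slot deltaBands wavelengths (nm) where the endmembers diverge.
#' @slot noiseSd multiplicative noise SD as a fraction of signal.
#' @slot darkLevel sensor dark offset in counts.
#' @slot whiteFill white-reference peak as a fraction of 4095.
#' @slot bandScaleDrift maximum relative magnification across bands.
#' @slot halationProb,shadowProb per-image artifact probabilities.
#' @slot minSeparation required endmember separation at the delta bands, as
#'   a multiple of the per-band noise SD.
#' @slot quantize quantize counts to integers (off for analytic phantoms).
#' @slot seed cohort seed.
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer",
                 wavelengths = "numeric", nAnimals = "integer",
                 tumorRadiusPx = "numeric", endmemberNormal = "numeric",
                 endmemberTumor = "numeric", deltaBands = "numeric",
                 noiseSd = "numeric", darkLevel = "numeric",
                 whiteFill = "numeric", bandScaleDrift = "numeric",
                 halationProb = "numeric", shadowProb = "numeric",
                 minSeparation = "numeric", quantize = "logical",
                 seed = "integer"),
  validity = function(object) {
    B <- length(object@wavelengths)
    if (length(object@endmemberNormal) != B ||
        length(object@endmemberTumor) != B)
      return("endmembers must have one reflectance per band")
    if (any(object@endmemberNormal <= 0) || any(object@endmemberNormal > 1) ||
        any(object@endmemberTumor <= 0) || any(object@endmemberTumor > 1))
      return("endmember reflectances must lie in (0, 1]")
    if (object@whiteFill <= 0 || object@whiteFill > 1)
      return("whiteFill must lie in (0, 1]")
    if (object@bandScaleDrift < 0) return("bandScaleDrift must be >= 0")
    if (length(object@tumorRadiusPx) != 2 || any(object@tumorRadiusPx <= 0))
      return("tumorRadiusPx must be a positive (min, max) pair")
    if (object@noiseSd > 0 && object@minSeparation > 0) {
      db <- match(object@deltaBands, object@wavelengths)
      if (anyNA(db)) return("deltaBands must be members of the wavelength axis")
      gap <- abs(object@endmemberNormal[db] - object@endmemberTumor[db])
      need <- object@minSeparation * object@noiseSd * object@endmemberNormal[db]
      if (any(gap <= need))
        return("endmember separation at the delta bands must exceed minSeparation x noise")
    }
    TRUE
  })
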