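#' @include AllClasses.R
NULL

#' Apply a band-to-band registration to a cube
#'
#' Resamples every non-reference band under its scale-about-center +
#' translation transform; the reference band passes through untouched.
#' The validity mask shrinks wherever resampling would read outside the
#' frame.  Counts cubes get out-of-frame pixels filled with 0 (counts
#' never carry NaN) and marked invalid; absorbance cubes get NaN.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param reg a \linkS4class{BandRegistration} with one parameter set per
#'   band of \code{cube}.
#' @return the registered \linkS4class{SpectralCube}.
#' @export
applyRegistration <- function(cube, reg) {
  B <- nBands(cube)
  if (length(reg@scale) != B)
    stop("registration must carry one parameter set per band")
  if (any(reg@scale <= 0)) stop("registration scale must be > 0")
  v <- cube@values
  out <- v
  lost <- matrix(FALSE, dim(v)[1], dim(v)[2])
  for (b in seq_len(B)) {
    if (reg@scale[b] == 1 && reg@tx[b] == 0 && reg@ty[b] == 0) next
    rb <- resampleBand(v[, , b], reg@scale[b], reg@tx[b], reg@ty[b],
                       interpolation = reg@interpolation)
    lost <- lost | is.na(rb) & !is.na(v[, , b])
    out[, , b] <- rb
  }
  valid <- cube@valid & !lost
  if (cubeSpace(cube) == "counts") {
    out[is.na(out)] <- 0
    out <- clampCounts(out, 2^cube@bitDepth - 1)  # guard fp overshoot of interpolation
  } else {
    out[array(!valid, dim = dim(out))] <- NaN
  }
  spectralCube(out, cube@wavelengths, bitDepth = cube@bitDepth, valid = valid,
               space = cubeSpace(cube))
}

## Normalized cross-correlation between a candidate-transformed band and
## the (pre-blurred) reference, inside a margin.  Both images are smoothed
## with the same mild Gaussian before correlating: interpolation smooths
## sensor noise by a scale-dependent amount, which otherwise biases the
## NCC maximizer away from the true geometric alignment.
nccScore <- function(band, refBlur, scale, tx, ty, margin = 8L, preblur = 1) {
  r <- resampleBand(band, scale, tx, ty)
  bad <- is.na(r)
  if (any(bad)) r[bad] <- mean(r, na.rm = TRUE)  # borders; excluded by margin
  rb <- gaussianBlur(r, preblur)
  H <- nrow(refBlur); W <- ncol(refBlur)
  keep <- matrix(FALSE, H, W)
  keep[(margin + 1):(H - margin), (margin + 1):(W - margin)] <- TRUE
  a <- rb[keep]; bref <- refBlur[keep]
  if (length(a) < 16 || sd(a) == 0 || sd(bref) == 0) return(-Inf)
  cor(a, bref)
}

#' Estimate per-band registration against a reference band
#'
#' Recovers, for every band, the scale + translation that best aligns it
#' to the reference band (the widest-field 1000 nm band), by maximizing
#' normalized cross-correlation over a coarse scale grid followed by
#' Nelder-Mead refinement of (scale, tx, ty).  Intended for cubes with
#' strong shared structure across bands.
#'
#' @param cube a \linkS4class{SpectralCube} (counts or absorbance).
#' @param referenceBand reference band index (default 1).
#' @param scaleRange search interval for the correcting scale.
#' @param scaleStep coarse-grid step.
#' @param interpolation resampling kernel recorded in the result.
#' @return a \linkS4class{BandRegistration}.
#' @export
estimateRegistration <- function(cube, referenceBand = 1L,
                                 scaleRange = c(0.95, 1.05),
                                 scaleStep = 0.005,
                                 interpolation = "bilinear") {
  B <- nBands(cube)
  v <- cube@values
  ref <- v[, , referenceBand]
  if (sd(ref) == 0) stop("cannot register: reference band is featureless")
  refBlur <- gaussianBlur(ref, 1)
  scale <- rep(1, B); tx <- rep(0, B); ty <- rep(0, B)
  grid <- seq(scaleRange[1], scaleRange[2], by = scaleStep)
  for (b in seq_len(B)) {
    if (b == referenceBand) next
    band <- v[, , b]
    if (sd(band) == 0)
      stop(sprintf("cannot register: band %d is featureless (constant image)", b))
    coarse <- vapply(grid, function(s) nccScore(band, refBlur, s, 0, 0), 0)
    s0 <- grid[which.max(coarse)]
    fit <- optim(c(s0, 0, 0),
                 function(p) -nccScore(band, refBlur, p[1], p[2], p[3]),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 400,
                                parscale = c(0.01, 1, 1)))
    scale[b] <- fit$par[1]; tx[b] <- fit$par[2]; ty[b] <- fit$par[3]
  }
  bandRegistration(scale = scale, tx = tx, ty = ty,
                   referenceBand = referenceBand,
                   interpolation = interpolation)
}

#' Registration implied by known phantom drift scales
#'
#' Converts the generator's forward per-band magnifications s_b into the
#' correcting registration (scale 1/s_b) that realigns each band to the
#' reference geometry.
#'
#' @param bandScales forward drift scales, one per band.
#' @param referenceBand reference band index.
#' @param interpolation resampling kernel.
#' @return a \linkS4class{BandRegistration}.
#' @export
registrationFromTruth <- function(bandScales, referenceBand = 1L,
                                  interpolation = "bilinear") {
  bandRegistration(scale = 1 / bandScales, tx = 0, ty = 0,
                   referenceBand = referenceBand, interpolation = interpolation)
}

#' Register all three cubes of a bundle
#'
#' Applies the same registration to raw, white and dark cubes so that the
#' absorbance calibration sees corresponding pixels.
#'
#' @param bundle a \linkS4class{CubeBundle}.
#' @param reg a \linkS4class{BandRegistration}.
#' @return the registered \linkS4class{CubeBundle}.
#' @export
registerBundle <- function(bundle, reg) {
  cubeBundle(applyRegistration(bundle@raw, reg),
             applyRegistration(bundle@white, reg),
             applyRegistration(bundle@dark, reg),
             labels = bundle@labels, animalId = bundle@animalId,
             session = bundle@session)
}
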