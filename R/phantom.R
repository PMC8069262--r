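#' @include AllClasses.R
NULL

MAX_COUNT <- 4095   # 12-bit sensor dynamic range

#' The 14 acquisition band centers (nm)
#'
#' Band centers of the bandpass-filter set spanning 1000-1400 nm.
#' @return numeric vector of 14 ascending wavelengths.
#' @export
otnWavelengths <- function() {
  c(1000, 1030, 1050, 1070, 1100, 1150, 1200, 1225, 1250,
    1300, 1320, 1350, 1370, 1400)
}

## Smooth water-like normal-tissue absorbance rising toward 1400 nm with a
## mild overtone bump near 1200 nm; reflectance = 10^-A.
normalEndmember <- function(wl) {
  A <- 0.20 + 0.55 * ((wl - 1000) / 400)^1.6 + 0.08 * exp(-((wl - 1200) / 70)^2)
  10^(-A)
}

## Tumor endmember: the normal endmember depressed by Gaussian bumps (in
## wavelength) centered at the delta bands; `relDepth` is the relative
## reflectance deficit at each bump peak.
tumorEndmember <- function(wl, deltaBands, relDepth) {
  bump <- rep(0, length(wl))
  for (d in deltaBands) bump <- pmax(bump, exp(-((wl - d) / 25)^2))
  normalEndmember(wl) * (1 - relDepth * bump)
}

#' Construct a PhantomSpec
#'
#' Defaults describe the emulated study: 9 animals, 320 x 256 px 12-bit
#' frames, the 14-band 1000-1400 nm axis, white reference exposed to 90%
#' of the 4095 dynamic range, tumor/normal reflectance endmembers that
#' diverge near 1070, 1250 and 1400 nm, 1% multiplicative noise, and a
#' band-dependent magnification drift of up to 2% (a few pixels at the
#' frame edge) relative to the widest-field 1000 nm band.
#'
#' @param height,width frame size in px (default 256 x 320).
#' @param wavelengths band centers in nm (default \code{otnWavelengths()}).
#' @param nAnimals cohort size (default 9).
#' @param tumorRadiusPx (min, max) tumor semi-axis in px.
#' @param tumorContrast endmember reflectance deficit at the delta bands,
#'   as a multiple of \code{noiseSd} (default 3: comfortably detectable).
#' @param endmemberNormal,endmemberTumor optional explicit reflectance
#'   endmembers, one value in (0,1] per band.
#' @param deltaBands wavelengths (nm) where the classes diverge.
#' @param noiseSd multiplicative noise SD as a fraction of signal.
#' @param darkLevel sensor dark offset in counts.
#' @param whiteFill white-reference peak as a fraction of 4095.
#' @param bandScaleDrift maximum relative magnification across bands.
#' @param halationProb,shadowProb per-image probabilities of a saturated
#'   (halation) or near-dark (shadow) patch.
#' @param minSeparation validity floor on the endmember gap at the delta
#'   bands, as a multiple of the per-band noise SD.
#' @param quantize quantize counts to integers (default TRUE; disable for
#'   analytic noiseless phantoms).
#' @param seed cohort seed.
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(height = 64L, width = 80L, nAnimals = 2L)
#' cohort <- generateCohort(spec)
#' length(cohort)
#' @export
phantomSpec <- function(height = 256L, width = 320L,
                        wavelengths = otnWavelengths(), nAnimals = 9L,
                        tumorRadiusPx = NULL, tumorContrast = 3,
                        endmemberNormal = NULL, endmemberTumor = NULL,
                        deltaBands = c(1070, 1250, 1400), noiseSd = 0.01,
                        darkLevel = 100, whiteFill = 0.90,
                        bandScaleDrift = 0.02, halationProb = 0.1,
                        shadowProb = 0.1, minSeparation = 0.1,
                        quantize = TRUE, seed = 1L) {
  if (is.null(tumorRadiusPx))
    tumorRadiusPx <- pmax(c(0.04, 0.06) * min(height, width), c(3, 4))
  if (is.null(endmemberNormal)) endmemberNormal <- normalEndmember(wavelengths)
  if (is.null(endmemberTumor)) {
    relDepth <- tumorContrast * max(noiseSd, 1e-3)
    endmemberTumor <- tumorEndmember(wavelengths, deltaBands, relDepth)
  }
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      wavelengths = as.numeric(wavelengths), nAnimals = as.integer(nAnimals),
      tumorRadiusPx = as.numeric(tumorRadiusPx),
      endmemberNormal = endmemberNormal, endmemberTumor = endmemberTumor,
      deltaBands = as.numeric(deltaBands), noiseSd = noiseSd,
      darkLevel = darkLevel, whiteFill = whiteFill,
      bandScaleDrift = bandScaleDrift, halationProb = halationProb,
      shadowProb = shadowProb, minSeparation = minSeparation,
      quantize = quantize, seed = as.integer(seed))
}

#' Generate one synthetic animal acquisition
#'
#' Composes raw = dark + reflectance x (white - dark) per band under a
#' smooth vignetted illumination, with multiplicative noise, optional
#' halation/shadow artifacts, and a per-band magnification drift relative
#' to the widest-field first band.  The returned ground truth carries the
#' exact label mask (in reference geometry) and the per-band drift scales.
#'
#' Labels are conservative: the tumor label is eroded inside the true
#' tumor ellipse and the normal label is a band-of-the-back strip kept
#' clear of the tumor, emulating expert-drawn ROIs that avoid ambiguous
#' boundary pixels.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param animalId animal identifier string.
#' @param session "pre_implant" (no tumor) or "post_implant".
#' @param seed integer seed for this acquisition.
#' @return list with \code{bundle} (a \linkS4class{CubeBundle}, labels
#'   attached) and \code{truth} (list: labels, bandScales, bodyMask,
#'   tumorMask).
#' @export
generateAnimal <- function(spec, animalId, session = c("post_implant", "pre_implant"),
                           seed = spec@seed) {
  session <- match.arg(session)
  H <- spec@height; W <- spec@width
  wl <- spec@wavelengths; B <- length(wl)
  withSeed(seed, {
    ## geometry -----------------------------------------------------------
    cy <- (H - 1) / 2 + runif(1, -0.03, 0.03) * H
    cx <- (W - 1) / 2 + runif(1, -0.03, 0.03) * W
    ry <- 0.36 * H * runif(1, 0.92, 1.05)
    rx <- 0.40 * W * runif(1, 0.92, 1.05)
    body <- ellipseMask(H, W, cy, cx, ry, rx)
    tumorMask <- matrix(FALSE, H, W)
    tumorLabel <- matrix(FALSE, H, W)
    if (session == "post_implant") {
      tr <- runif(1, spec@tumorRadiusPx[1], spec@tumorRadiusPx[2])
      trx <- tr * runif(1, 0.9, 1.25)
      placed <- FALSE
      for (try in 1:50) {
        tcy <- cy + runif(1, -0.6, 0.6) * (ry - tr - 2)
        tcx <- cx + runif(1, -0.6, 0.6) * (rx - trx - 2)
        cand <- ellipseMask(H, W, tcy, tcx, tr, trx)
        inner <- ellipseMask(H, W, cy, cx, ry - 2, rx - 2)
        if (all(inner[cand])) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place the tumor inside the body")
      tumorMask <- cand
      tumorLabel <- ellipseMask(H, W, tcy, tcx, max(tr - 1.5, 1), max(trx - 1.5, 1))
    }
    ## conservative normal ROI: central strip of the body, eroded, clear of
    ## the tumor neighborhood
    innerBody <- ellipseMask(H, W, cy, cx, ry - 3, rx - 3)
    rows <- matrix(0:(H - 1), H, W)
    strip <- innerBody & abs(rows - cy) <= 0.45 * ry
    if (session == "post_implant") {
      tumorHalo <- if (any(tumorMask)) {
        ii <- which(tumorMask, arr.ind = TRUE)
        ellipseMask(H, W, mean(ii[, 1] - 1), mean(ii[, 2] - 1),
                    diff(range(ii[, 1])) / 2 + 4, diff(range(ii[, 2])) / 2 + 4)
      } else matrix(FALSE, H, W)
      strip <- strip & !tumorHalo
    }
    labels <- matrix(0L, H, W)
    labels[strip] <- 1L
    labels[tumorLabel] <- 2L

    ## illumination + reference-geometry composition ----------------------
    rr <- matrix(0:(H - 1), H, W); cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
    rn2 <- ((rr - (H - 1) / 2) / (H / 2))^2 + ((cc - (W - 1) / 2) / (W / 2))^2
    vignette <- 1 - 0.25 * rn2 / max(rn2)
    whitePeak <- spec@whiteFill * MAX_COUNT
    refl <- array(0.03, c(H, W, B))   # dim background reflectance
    for (b in seq_len(B)) {
      plane <- matrix(0.03, H, W)
      plane[body] <- spec@endmemberNormal[b]
      plane[tumorMask] <- spec@endmemberTumor[b]
      refl[, , b] <- plane
    }
    whiteRef <- whitePeak * vignette
    raw <- array(0, c(H, W, B)); white <- array(0, c(H, W, B))
    dark <- array(spec@darkLevel, c(H, W, B))
    sB <- 1 + spec@bandScaleDrift * (seq_len(B) - 1) / max(B - 1, 1)
    for (b in seq_len(B)) {
      rawPlane <- spec@darkLevel + refl[, , b] * (whiteRef - spec@darkLevel)
      whitePlane <- whiteRef
      if (sB[b] != 1) {      # band b sees a magnified scene (narrower FOV)
        rawPlane <- resampleBand(rawPlane, sB[b])
        whitePlane <- resampleBand(whitePlane, sB[b])
      }
      raw[, , b] <- rawPlane
      white[, , b] <- whitePlane
    }
    ## noise ---------------------------------------------------------------
    if (spec@noiseSd > 0) {
      raw <- raw * (1 + spec@noiseSd * array(rnorm(H * W * B), c(H, W, B)))
      ## white reference is frame-averaged in practice: lower noise so the
      ## per-band peak stays within 2% of the exposure target
      white <- white * (1 + 0.3 * spec@noiseSd * array(rnorm(H * W * B), c(H, W, B)))
      dark <- dark + array(rnorm(H * W * B, sd = 1.5), c(H, W, B))
    }
    ## artifacts -----------------------------------------------------------
    if (spec@halationProb > 0 && runif(1) < spec@halationProb) {
      hy <- runif(1, 0.2, 0.8) * H; hx <- runif(1, 0.2, 0.8) * W
      halo <- ellipseMask(H, W, hy, hx, 0.02 * H + 2, 0.02 * W + 2)
      for (b in seq_len(B)) { pl <- raw[, , b]; pl[halo] <- MAX_COUNT; raw[, , b] <- pl }
    }
    if (spec@shadowProb > 0 && runif(1) < spec@shadowProb) {
      sy <- runif(1, 0.2, 0.8) * H; sx <- runif(1, 0.2, 0.8) * W
      sh <- ellipseMask(H, W, sy, sx, 0.04 * H + 2, 0.04 * W + 2)
      for (b in seq_len(B)) {
        pl <- raw[, , b]
        pl[sh] <- spec@darkLevel + 0.02 * (pl[sh] - spec@darkLevel)
        raw[, , b] <- pl
      }
    }
    raw <- clampCounts(raw, MAX_COUNT)
    white <- clampCounts(white, MAX_COUNT)
    dark <- clampCounts(dark, MAX_COUNT)
    if (spec@quantize) { raw <- round(raw); white <- round(white); dark <- round(dark) }

    bundle <- cubeBundle(spectralCube(raw, wl), spectralCube(white, wl),
                         spectralCube(dark, wl), labels = labels,
                         animalId = animalId, session = session)
    list(bundle = bundle,
         truth = list(labels = labels, bandScales = sB, bodyMask = body,
                      tumorMask = tumorMask))
  })
}

#' Generate a synthetic cohort of pre/post-implantation acquisition pairs
#'
#' @param spec a \linkS4class{PhantomSpec}; per-animal seeds derive
#'   deterministically from \code{spec@seed}, so identical specs give
#'   identical cohorts.
#' @return list of length \code{nAnimals}; each element has
#'   \code{animalId}, \code{pre}, \code{post} (generateAnimal results).
#' @export
generateCohort <- function(spec) {
  lapply(seq_len(spec@nAnimals), function(a) {
    id <- sprintf("m%02d", a)
    list(animalId = id,
         pre = generateAnimal(spec, id, "pre_implant",
                              seed = deriveSeed(spec@seed, id, "pre")),
         post = generateAnimal(spec, id, "post_implant",
                               seed = deriveSeed(spec@seed, id, "post")))
  })
}

#' Generate a synthetic three-bar resolution target cube
#'
#' Square-wave three-bar elements (bars vertical) at each requested spatial
#' frequency, stacked down the frame, Gaussian-blurred per band; the
#' element metadata maps each element to its frequency and pixel bounds so
#' contrast can be measured per element.
#'
#' @param lpPerMm spatial frequencies of the elements (line pairs per mm).
#' @param mmPerPx pixel pitch in mm.
#' @param blurSdPerBand Gaussian blur SD in px, one per band.
#' @param contrast amplitude of the bar pattern in [0,1]; bars sit at
#'   0.5 + contrast/2, background at 0.5 - contrast/2 so the ideal
#'   Michelson contrast equals \code{contrast}.
#' @param wavelengths band centers (default one per blur entry, 1000 nm up).
#' @return list with \code{cube} (a \linkS4class{SpectralCube}, values in
#'   [0,1]) and \code{elements} (data.frame: element, lp_per_mm, row0,
#'   row1, col0, col1; 0-based inclusive bounds of the element plus one
#'   bar-width margin).
#' @export
generateBarTarget <- function(lpPerMm, mmPerPx, blurSdPerBand, contrast = 1,
                              wavelengths = NULL) {
  if (any(lpPerMm <= 0)) stop("bar frequencies must be positive")
  if (any(blurSdPerBand < 0)) stop("per-band blur must be >= 0")
  periodPx <- 1 / (lpPerMm * mmPerPx)
  if (any(periodPx < 1))
    stop("bars below 1 px period are unrepresentable at this pixel pitch")
  B <- length(blurSdPerBand)
  if (is.null(wavelengths)) wavelengths <- seq(1000, by = 50, length.out = B)
  lo <- 0.5 - contrast / 2; hi <- 0.5 + contrast / 2
  margin <- 8L
  heights <- pmax(as.integer(ceiling(5 * periodPx / 2)), 5L)
  H <- sum(heights + 2L * margin)
  W <- as.integer(ceiling(max(5 * periodPx / 2))) + 6L * margin
  base <- matrix(lo, H, W)
  meta <- data.frame(element = seq_along(lpPerMm), lp_per_mm = lpPerMm,
                     row0 = NA_integer_, row1 = NA_integer_,
                     col0 = NA_integer_, col1 = NA_integer_)
  top <- 0L
  for (e in seq_along(lpPerMm)) {
    w <- periodPx[e] / 2                    # bar width in px
    r0 <- top + margin; r1 <- r0 + heights[e] - 1L
    c0 <- 2L * margin
    for (k in 0:2) {                        # three bars, bar/gap = w
      cs <- c0 + k * 2 * w
      cols <- which(seq_len(W) - 1 >= cs & seq_len(W) - 1 < cs + w)
      base[(r0:r1) + 1L, cols] <- hi
    }
    ext <- max(1, floor(w))                 # one bar-width margin
    meta$row0[e] <- r0; meta$row1[e] <- r1
    meta$col0[e] <- max(c0 - ext, 0L)
    meta$col1[e] <- min(as.integer(ceiling(c0 + 5 * w - 1)) + ext, W - 1L)
    top <- r1 + margin + 1L
  }
  v <- array(0, c(H, W, B))
  for (b in seq_len(B)) v[, , b] <- gaussianBlur(base, blurSdPerBand[b])
  cube <- spectralCube(v, wavelengths, bitDepth = 12L, space = "counts")
  list(cube = cube, elements = meta)
}
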