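#' @include AllClasses.R
NULL

RAYLEIGH_CONTRAST <- 0.26   # bars count as resolved above this contrast

## Collapse an element region to a 1-d profile perpendicular to the bars
## (mean along the bar length), then find local extrema on the
## run-compressed profile so square-wave plateaus count once.
profileExtrema <- function(profile) {
  r <- rle(profile)
  v <- r$values
  n <- length(v)
  if (n < 3) return(list(maxima = numeric(0), minima = numeric(0)))
  isMax <- isMin <- rep(FALSE, n)
  for (k in 2:(n - 1)) {
    if (v[k] > v[k - 1] && v[k] > v[k + 1]) isMax[k] <- TRUE
    if (v[k] < v[k - 1] && v[k] < v[k + 1]) isMin[k] <- TRUE
  }
  maxPos <- which(isMax)
  if (length(maxPos) < 2) return(list(maxima = v[maxPos], minima = numeric(0)))
  inner <- which(isMin & seq_len(n) > min(maxPos) & seq_len(n) < max(maxPos))
  list(maxima = v[maxPos], minima = v[inner])
}

#' Michelson contrast of one bar element
#'
#' Takes the intensity profile perpendicular to the bars (averaged along
#' the full bar length), sets Imax to the mean of the profile's local
#' maxima and Imin to the mean of the local minima between them, and
#' returns (Imax - Imin) / (Imax + Imin).  With \code{strictExtrema} the
#' raw single-pixel extrema are used instead of extrema means.
#'
#' @param region numeric matrix covering a three-bar element.
#' @param orientation bar orientation: "vertical" bars vary across columns.
#' @param strictExtrema use the profile's global max/min (noise-fragile;
#'   default FALSE).
#' @return contrast in [0, 1]; 0 with attribute unresolvable = TRUE when
#'   fewer than 2 maxima or no interior minimum survives the blur.
#' @export
elementContrast <- function(region, orientation = c("vertical", "horizontal"),
                            strictExtrema = FALSE) {
  orientation <- match.arg(orientation)
  profile <- if (orientation == "vertical") colMeans(region) else rowMeans(region)
  if (strictExtrema) {
    imax <- max(profile); imin <- min(profile)
    if (imax == imin) {
      out <- 0; attr(out, "unresolvable") <- TRUE; return(out)
    }
    return((imax - imin) / (imax + imin))
  }
  ex <- profileExtrema(profile)
  if (length(ex$maxima) < 2 || length(ex$minima) < 1) {
    out <- 0
    attr(out, "unresolvable") <- TRUE
    return(out)
  }
  imax <- mean(ex$maxima); imin <- mean(ex$minima)
  (imax - imin) / (imax + imin)
}

#' Contrast-transfer resolution analysis of a bar-target cube
#'
#' Michelson contrast of every element in every band, with the Rayleigh
#' resolution call (resolved when contrast > 0.26) and, per band, the
#' finest resolved spatial frequency (NA when no element is resolved).
#'
#' @param cube bar-target \linkS4class{SpectralCube} from
#'   \code{\link{generateBarTarget}} (or a measured equivalent).
#' @param elements element metadata data.frame (element, lp_per_mm, row0,
#'   row1, col0, col1; 0-based inclusive bounds).
#' @param orientation bar orientation.
#' @return list: \code{table} (data.frame band, wavelength_nm, element,
#'   lp_per_mm, contrast, resolved), \code{finestResolved} (data.frame
#'   band, wavelength_nm, lp_per_mm).
#' @export
resolutionCurve <- function(cube, elements, orientation = "vertical") {
  B <- nBands(cube)
  rows <- list()
  for (b in seq_len(B)) for (e in seq_len(nrow(elements))) {
    el <- elements[e, ]
    region <- cube@values[(el$row0:el$row1) + 1L, (el$col0:el$col1) + 1L, b]
    ct <- elementContrast(region, orientation)
    rows[[length(rows) + 1L]] <-
      data.frame(band = b, wavelength_nm = cube@wavelengths[b],
                 element = el$element, lp_per_mm = el$lp_per_mm,
                 contrast = as.numeric(ct),
                 resolved = as.numeric(ct) > RAYLEIGH_CONTRAST)
  }
  tab <- do.call(rbind, rows)
  finest <- do.call(rbind, lapply(seq_len(B), function(b) {
    sub <- tab[tab$band == b & tab$resolved, ]
    data.frame(band = b, wavelength_nm = cube@wavelengths[b],
               lp_per_mm = if (nrow(sub)) max(sub$lp_per_mm) else NA_real_)
  }))
  list(table = tab, finestResolved = finest)
}
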