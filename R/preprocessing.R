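#' @include AllClasses.R
NULL

#' Standard normal variate (SNV) transform of a spectrum
#'
#' Centers a spectrum to mean 0 and scales it to unit standard deviation,
#' removing additive baselines and multiplicative scatter: Z = (x -
#' mean(x)) / std(x).  The sample-SD (n - 1) convention is the default, as
#' is standard in chemometrics; population SD is available for sensitivity
#' checks.
#'
#' @param x numeric spectrum, length >= 2, finite, non-constant.
#' @param sdType "sample" (n - 1, default) or "population" (n).
#' @return the SNV-transformed spectrum (mean 0, SD 1).
#' @examples
#' snv(c(1, 2, 3))   # -1 0 1
#' @export
snv <- function(x, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  if (length(x) < 2) stop("SNV requires at least 2 bands")
  if (any(!is.finite(x))) stop("SNV input must be finite (NaN present)")
  s <- sd(x)
  if (sdType == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (s == 0) stop("degenerate spectrum: constant input has no SNV transform")
  (x - mean(x)) / s
}

## Row-wise SNV of a matrix; rows must be pre-screened as non-constant.
snvRows <- function(X, sdType = "sample") {
  n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  ss <- sqrt(rowSums(Xc^2) / (n - 1))
  if (sdType == "population") ss <- ss * sqrt((n - 1) / n)
  Xc / ss
}

#' Assemble a labeled pixel dataset from absorbance cubes
#'
#' One row per labeled, valid pixel: the SNV of its absorbance spectrum.
#' Pixels invalidated by the calibration exclusion, and pixels with
#' constant spectra (SNV undefined), never enter the dataset.  Rows are
#' sorted by (animalId, row, col) so assembly is order-deterministic.
#'
#' @param cubes list of absorbance \linkS4class{SpectralCube}s.
#' @param labels list of integer label masks (0/1/2), aligned with
#'   \code{cubes}.
#' @param animalIds character vector, one id per cube.
#' @param sdType SNV SD convention, see \code{\link{snv}}.
#' @return a \linkS4class{PixelDataset} (label 0 = normal, 1 = tumor).
#' @export
buildDataset <- function(cubes, labels, animalIds, sdType = "sample") {
  stopifnot(length(cubes) == length(labels), length(cubes) == length(animalIds))
  parts <- vector("list", length(cubes))
  wl <- NULL
  for (k in seq_along(cubes)) {
    cube <- cubes[[k]]
    if (cubeSpace(cube) != "absorbance")
      stop("datasets are built from absorbance cubes")
    if (is.null(wl)) wl <- wavelengths(cube)
    else if (!isTRUE(all.equal(wl, wavelengths(cube))))
      stop("all cubes must share one wavelength axis")
    mask <- labels[[k]]
    if (!identical(dim(mask), dim(cube@values)[1:2]))
      stop("label mask dimensions must match the cube")
    sel <- which(mask > 0L & cube@valid, arr.ind = TRUE)
    if (nrow(sel) == 0) { parts[[k]] <- NULL; next }
    ## deterministic order: by row then col (0-based indices reported)
    sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
    B <- nBands(cube)
    X <- matrix(cube@values[cbind(sel[rep(seq_len(nrow(sel)), B), , drop = FALSE],
                                  rep(seq_len(B), each = nrow(sel)))],
                nrow = nrow(sel), ncol = B)
    keep <- apply(X, 1, function(r) all(is.finite(r)) && sd(r) > 0)
    if (!any(keep)) { parts[[k]] <- NULL; next }
    X <- X[keep, , drop = FALSE]
    sel <- sel[keep, , drop = FALSE]
    parts[[k]] <- list(X = snvRows(X, sdType),
                       y = as.integer(mask[sel] == 2L),
                       id = rep(animalIds[k], nrow(sel)),
                       px = cbind(sel[, 1] - 1L, sel[, 2] - 1L))
  }
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0) stop("zero labeled valid pixels: cannot build a dataset")
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  y <- unlist(lapply(parts, `[[`, "y"))
  id <- unlist(lapply(parts, `[[`, "id"))
  px <- do.call(rbind, lapply(parts, `[[`, "px"))
  o <- order(id, px[, 1], px[, 2])
  new("PixelDataset", X = X[o, , drop = FALSE], y = as.integer(y[o]),
      animalId = id[o], pixelIndex = px[o, , drop = FALSE], wavelengths = wl)
}

#' Per-animal, per-class mean SNV spectra
#'
#' The arithmetic mean of the SNV rows of each (animal, class) cell; a
#' missing class for an animal is flagged absent (NA spectrum).
#'
#' @param dataset a \linkS4class{PixelDataset}.
#' @return data.frame with columns animal_id, class ("normal"/"tumor"),
#'   present, n, and one column per band (named wl_<nm>).
#' @export
meanClassSpectra <- function(dataset) {
  ids <- sort(unique(dataset@animalId))
  classes <- c(normal = 0L, tumor = 1L)
  wl <- dataset@wavelengths
  rows <- list()
  for (id in ids) for (cl in names(classes)) {
    sel <- dataset@animalId == id & dataset@y == classes[[cl]]
    n <- sum(sel)
    spec <- if (n > 0) colMeans(dataset@X[sel, , drop = FALSE]) else
      rep(NA_real_, length(wl))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(animal_id = id, class = cl, present = n > 0, n = n),
            as.data.frame(as.list(setNames(spec, sprintf("wl_%g", wl)))))
  }
  do.call(rbind, rows)
}
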