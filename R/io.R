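#' @include accessors.R
NULL

## On-disk dialect: a multi-page TIFF (one band per page) plus a JSON
## sidecar with the wavelength axis, bit depth and value space.  Counts
## cubes with integral values are stored as 16-bit unsigned samples;
## everything else is stored as 32-bit float after an affine map into
## [0, 0.9] recorded in the sidecar (value_offset/value_scale), with 1.0
## reserved as the NaN sentinel.  When the validity mask is non-trivial it
## is appended as an extra page and flagged in the sidecar.

NAN_SENTINEL <- 1.0
FLOAT_SPAN <- 0.9

#' Write a SpectralCube to a multi-page TIFF plus JSON sidecar
#'
#' Integer counts cubes round-trip bit-exactly; float cubes round-trip
#' within 32-bit float representation (about 1e-7 relative), with NaN at
#' excluded pixels preserved.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param stackPath output TIFF path.
#' @param sidecarPath output JSON sidecar path (default: stackPath with a
#'   .json extension).
#' @param registration optional \linkS4class{BandRegistration} to record in
#'   the sidecar.
#' @return invisibly, c(stackPath, sidecarPath).
#' @export
writeCube <- function(cube, stackPath, sidecarPath = NULL, registration = NULL) {
  if (is.null(sidecarPath)) sidecarPath <- paste0(sub("\\.[^.]+$", "", stackPath), ".json")
  v <- cube@values
  d <- dim(v)
  integral <- cube@space == "counts" && !anyNA(v) && all(v == round(v))
  side <- list(wavelengths_nm = cube@wavelengths,
               bit_depth = cube@bitDepth,
               space = cube@space,
               storage = if (integral) "uint16" else "float32")
  pages <- vector("list", d[3])
  if (integral) {
    for (b in seq_len(d[3])) pages[[b]] <- v[, , b] / 65535
    bits <- 16L
  } else {
    fin <- v[is.finite(v)]
    lo <- if (length(fin)) min(fin) else 0
    hi <- if (length(fin)) max(fin) else 1
    scl <- if (hi > lo) (hi - lo) / FLOAT_SPAN else 1
    side$value_offset <- lo
    side$value_scale <- scl
    for (b in seq_len(d[3])) {
      pg <- (v[, , b] - lo) / scl
      pg[!is.finite(pg)] <- NAN_SENTINEL
      pages[[b]] <- pg
    }
    bits <- 32L
  }
  if (!all(cube@valid)) {
    side$has_validity_page <- TRUE
    pages[[d[3] + 1L]] <- (cube@valid * 1) * if (integral) 1 / 65535 else 1
  }
  tryCatch(suppressWarnings(tiff::writeTIFF(pages, stackPath, bits.per.sample = bits)),
           error = function(e) stop("cannot write TIFF stack: ",
                                    conditionMessage(e), call. = FALSE))
  jsonlite::write_json(side, sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(c(stackPath, sidecarPath))
}

#' Read a SpectralCube written by \code{writeCube}
#'
#' @param stackPath multi-page TIFF, one band per page, all pages the same
#'   shape.
#' @param sidecarPath JSON sidecar listing wavelengths_nm (ascending, one
#'   per page), bit_depth and the storage encoding.
#' @return a \linkS4class{SpectralCube}.
#' @export
readCube <- function(stackPath, sidecarPath = NULL) {
  if (is.null(sidecarPath)) sidecarPath <- paste0(sub("\\.[^.]+$", "", stackPath), ".json")
  side <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  pages <- tiff::readTIFF(stackPath, all = TRUE, as.is = FALSE)
  wl <- as.numeric(side$wavelengths_nm)
  hasMask <- isTRUE(side$has_validity_page)
  B <- length(pages) - as.integer(hasMask)
  if (B != length(wl))
    stop("format error: TIFF has ", B, " band page(s) but sidecar lists ",
         length(wl), " wavelength(s)")
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("format error: sidecar wavelengths must be strictly increasing")
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), TRUE)))
    stop("format error: TIFF pages differ in shape")
  v <- array(0, c(shp[1], shp[2], B))
  if (identical(side$storage, "uint16")) {
    for (b in seq_len(B)) v[, , b] <- round(pages[[b]] * 65535)
    valid <- if (hasMask) round(pages[[B + 1L]] * 65535) >= 1 else
      matrix(TRUE, shp[1], shp[2])
  } else {
    lo <- as.numeric(side$value_offset); scl <- as.numeric(side$value_scale)
    for (b in seq_len(B)) {
      pg <- pages[[b]]
      pg[pg >= (NAN_SENTINEL + FLOAT_SPAN) / 2] <- NaN
      v[, , b] <- pg * scl + lo
    }
    valid <- if (hasMask) pages[[B + 1L]] >= 0.5 else matrix(TRUE, shp[1], shp[2])
  }
  spectralCube(v, wl, bitDepth = as.integer(side$bit_depth), valid = valid,
               space = side$space)
}

#' Read / write a label mask
#'
#' Masks are single-page 8-bit TIFFs whose pixel values are restricted to
#' 0 (unlabeled), 1 (normal) and 2 (tumor).
#'
#' @param path file path.
#' @return \code{readLabels}: an integer matrix; \code{writeLabels}: the
#'   path, invisibly.
#' @export
readLabels <- function(path) {
  pg <- tiff::readTIFF(path, all = TRUE)
  if (length(pg) != 1) stop("format error: label mask must be a single page")
  m <- round(pg[[1]] * 255)
  if (!all(m %in% 0:2))
    stop("format error: label values must be 0 (unlabeled), 1 (normal) or 2 (tumor)")
  storage.mode(m) <- "integer"
  m
}

#' @rdname readLabels
#' @param mask integer matrix with values in {0, 1, 2}.
#' @export
writeLabels <- function(mask, path) {
  if (!all(mask %in% 0:2))
    stop("format error: label values must be 0 (unlabeled), 1 (normal) or 2 (tumor)")
  tiff::writeTIFF(mask / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a per-animal metrics report
#'
#' Writes the familiar per-animal table — one row per animal plus a pooled
#' "total" row recomputed from summed confusion counts (never by averaging
#' percentages) — as a CSV with percentages rounded to one decimal for
#' display, alongside a JSON document retaining full precision and the raw
#' counts.
#'
#' @param report data.frame as returned by \code{\link{classificationMetrics}}
#'   / \code{\link{poolMetrics}}.
#' @param path output CSV path; the JSON twin gets a .json extension.
#' @return invisibly, c(csvPath, jsonPath).
#' @export
writeReport <- function(report, path) {
  jsonPath <- paste0(sub("\\.[^.]+$", "", path), ".json")
  cols <- c("animal_id", "tumor_px", "normal_px", "specificity_pct",
            "sensitivity_pct", "accuracy_pct")
  if (nrow(report) == 0) {
    disp <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    disp <- report[, cols]
    for (p in grep("_pct$", cols, value = TRUE)) disp[[p]] <- round(disp[[p]], 1)
  }
  utils::write.csv(disp, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, jsonPath, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(c(path, jsonPath))
}

#' Save / load an MLP model checkpoint as JSON
#'
#' @param model a \linkS4class{MLPModel}.
#' @param path JSON path.
#' @return \code{writeModel}: the path invisibly; \code{readModel}: a
#'   \linkS4class{MLPModel}.
#' @export
writeModel <- function(model, path) {
  ck <- list(layer_sizes = model@layerSizes,
             hidden_activation = model@hiddenActivation,
             dropout_rate = model@dropoutRate,
             seed = model@seed,
             weights = lapply(model@weights, function(w) as.numeric(w)),
             biases = lapply(model@biases, as.numeric))
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- as.integer(ck$layer_sizes)
  W <- lapply(seq_len(length(ls) - 1), function(l)
    matrix(as.numeric(ck$weights[[l]]), ls[l], ls[l + 1]))
  b <- lapply(seq_len(length(ls) - 1), function(l) as.numeric(ck$biases[[l]]))
  new("MLPModel", layerSizes = ls, weights = W, biases = b,
      hiddenActivation = ck$hidden_activation,
      dropoutRate = as.numeric(ck$dropout_rate), seed = as.integer(ck$seed))
}
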