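#' @importFrom stats rnorm runif sd cor optim setNames
#' @importFrom utils packageVersion write.csv
NULL

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so package randomness never perturbs the user session.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a base seed and a label
#'
#' Stable string hash (polynomial rolling hash mod 2^31 - 1) so that every
#' stochastic stage (per-animal generation, per-fold model initialization,
#' dropout, shuffling) gets an independent but reproducible stream from one
#' global seed.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return a single integer in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, ...) {
  s <- paste(c(as.character(as.integer(seed)), vapply(list(...), as.character, "")),
             collapse = "/")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h) + 1L
}

## ---- image primitives --------------------------------------------------
## Coordinate convention (used everywhere): row-major, origin at the
## top-left pixel CENTER, 0-based indices; geometric image center at
## ((H-1)/2, (W-1)/2).

## Separable Gaussian blur with edge replication; sigma in pixels.
gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(x, along) {
    n <- if (along == 1) nrow(x) else ncol(x)
    out <- 0
    for (o in (-r):r) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + k[o + r + 1L] * (if (along == 1) x[idx, , drop = FALSE]
                                    else x[, idx, drop = FALSE])
    }
    out
  }
  blur1(blur1(m, 1), 2)
}

## Resample one band under the forward map q = scale * (p - c) + c + (tx, ty)
## (magnify about the image center, then translate; tx along columns, ty
## along rows).  Output pixel q is sampled at p = (q - c - t) / scale + c.
## Because the map is axis-separable the interpolation runs rows-then-cols.
## Samples falling outside the frame become NA.
resampleBand <- function(m, scale, tx = 0, ty = 0,
                         interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (scale <= 0) stop("registration scale must be > 0")
  H <- nrow(m); W <- ncol(m)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  ys <- ((0:(H - 1)) - cy - ty) / scale + cy
  xs <- ((0:(W - 1)) - cx - tx) / scale + cx
  if (interpolation == "nearest") {
    yi <- round(ys); xi <- round(xs)
    yok <- yi >= 0 & yi <= H - 1
    xok <- xi >= 0 & xi <= W - 1
    out <- matrix(NA_real_, H, W)
    out[yok, xok] <- m[yi[yok] + 1L, xi[xok] + 1L, drop = FALSE]
    return(out)
  }
  y0 <- floor(ys); fy <- ys - y0
  x0 <- floor(xs); fx <- xs - x0
  yok <- y0 >= 0 & y0 + 1 <= H - 1
  xok <- x0 >= 0 & x0 + 1 <= W - 1
  ## clamp the index arithmetic; invalid rows/cols are overwritten with NA
  y0c <- pmin(pmax(y0, 0), H - 2); x0c <- pmin(pmax(x0, 0), W - 2)
  m00 <- m[y0c + 1L, x0c + 1L, drop = FALSE]
  m10 <- m[y0c + 2L, x0c + 1L, drop = FALSE]
  m01 <- m[y0c + 1L, x0c + 2L, drop = FALSE]
  m11 <- m[y0c + 2L, x0c + 2L, drop = FALSE]
  wy <- matrix(fy, H, W); wx <- matrix(fx, H, W, byrow = TRUE)
  out <- (1 - wy) * (1 - wx) * m00 + wy * (1 - wx) * m10 +
    (1 - wy) * wx * m01 + wy * wx * m11
  out[!yok, ] <- NA_real_
  out[, !xok] <- NA_real_
  out
}

## Elliptical mask: TRUE inside ((r-cy)/ry)^2 + ((c-cx)/rx)^2 <= 1,
## 0-based pixel-center coordinates.
ellipseMask <- function(H, W, cy, cx, ry, rx) {
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
}

## round half away from zero is irrelevant here; base round() is fine for
## count quantization (values are non-negative).
clampCounts <- function(x, maxCount) pmin(pmax(x, 0), maxCount)
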