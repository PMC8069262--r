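test_that("absorbance calibration: unit reflectance, one decade, exclusion", {
  wl <- c(1000, 1200)
  mk <- function(vals) flatCube(vals, H = 3L, W = 3L, wl = wl)
  # Ir = Iw, Id = 0 -> A = 0
  a0 <- computeAbsorbance(cubeBundle(mk(c(3000, 3500)), mk(c(3000, 3500)),
                                     mk(c(0, 0))))
  expect_equal(max(abs(cubeValues(a0))), 0)
  # Ir - Id = 0.1 x (Iw - Id) -> A = 1 exactly
  a1 <- computeAbsorbance(cubeBundle(mk(c(460, 460)), mk(c(3700, 3700)),
                                     mk(c(100, 100))))
  expect_equal(as.vector(cubeValues(a1)), rep(1, 18), tolerance = 1e-14)
  # Iw = Id at one band of one pixel -> that whole spectrum excluded
  raw <- array(2000, c(3, 3, 2)); white <- array(3600, c(3, 3, 2))
  dark <- array(100, c(3, 3, 2))
  white[2, 2, 1] <- 100    # denominator zero at band 1 only
  ax <- computeAbsorbance(cubeBundle(spectralCube(raw, wl),
                                     spectralCube(white, wl),
                                     spectralCube(dark, wl)))
  expect_false(validMask(ax)[2, 2])
  expect_true(all(is.nan(cubeValues(ax)[2, 2, ])))
  expect_equal(sum(!validMask(ax)), 1)
  expect_equal(sum(is.nan(cubeValues(ax))), 2)  # only that pixel, both bands
})

test_that("non-positive numerators are clamped, not excluded", {
  wl <- c(1000, 1200)
  raw <- array(50, c(2, 2, 2))      # below the dark level
  ax <- computeAbsorbance(cubeBundle(spectralCube(raw, wl),
                                     flatCube(c(3600, 3600), 2L, 2L, wl),
                                     flatCube(c(100, 100), 2L, 2L, wl)),
                          epsilon = 0.5)
  expect_true(all(validMask(ax)))
  expect_equal(as.vector(cubeValues(ax)), rep(-log10(0.5 / 3500), 8),
               tolerance = 1e-12)
})

test_that("absorbance is monotone non-increasing in raw counts", {
  set.seed(10)
  wl <- c(1000, 1100, 1200)
  white <- array(runif(2 * 2 * 3, 3000, 3900), c(2, 2, 3))
  dark <- array(runif(2 * 2 * 3, 50, 150), c(2, 2, 3))
  for (k in 1:20) {
    r1 <- array(runif(12, 200, 3000), c(2, 2, 3))
    r2 <- r1 + array(runif(12, 0, 500), c(2, 2, 3))
    a1 <- computeAbsorbance(cubeBundle(spectralCube(round(r1), wl),
                                       spectralCube(round(white), wl),
                                       spectralCube(round(dark), wl)))
    a2 <- computeAbsorbance(cubeBundle(spectralCube(round(r2), wl),
                                       spectralCube(round(white), wl),
                                       spectralCube(round(dark), wl)))
    expect_true(all(cubeValues(a2) <= cubeValues(a1) + 1e-12))
  }
})

test_that("space and shape contracts are enforced", {
  wl <- c(1000, 1200)
  ab <- absCube(array(0.5, c(2, 2, 2)), wl)
  ct <- flatCube(c(100, 100), 2L, 2L, wl)
  expect_error(computeAbsorbance(
    new("CubeBundle", raw = ab, white = ct, dark = ct, labels = NULL,
        animalId = "x", session = "pre_implant")), "counts")
  expect_error(cubeBundle(flatCube(c(1, 2), 2L, 2L), flatCube(c(1, 2), 3L, 3L),
                          flatCube(c(1, 2), 2L, 2L)), "share")
})

test_that("exposure check flags the 90% convention, saturation and underfill", {
  wl <- c(1000, 1200, 1400)
  v <- array(1000, c(3, 3, 3))
  v[1, 1, 1] <- 3686   # ~90% of 4095
  v[1, 1, 2] <- 4095   # saturated
  v[1, 1, 3] <- 2000   # underexposed
  rep <- checkExposure(spectralCube(v, wl))
  expect_equal(rep$fill_fraction[1], 3686 / 4095, tolerance = 1e-12)
  expect_lt(abs(rep$fill_fraction[1] - 0.90), 1.5e-3)
  expect_true(rep$pass[1]); expect_false(rep$saturated[1])
  expect_true(rep$saturated[2])
  expect_equal(rep$fill_fraction[3], 2000 / 4095, tolerance = 1e-12)
  expect_false(rep$pass[3])
})

test_that("invalid pixels propagate from input through every downstream product", {
  sp <- cleanSpec()
  an <- generateAnimal(sp, "m01", "post_implant", seed = 13L)
  bundle <- an$bundle
  bad <- matrix(TRUE, sp@height, sp@width); bad[10, 12] <- FALSE
  bundle@raw@valid <- bad
  a <- computeAbsorbance(bundle)
  expect_false(validMask(a)[10, 12])
  expect_true(all(is.nan(cubeValues(a)[10, 12, ])))
  # excluded from datasets even when labeled
  lab <- an$truth$labels
  lab[10, 12] <- 1L
  ds <- buildDataset(list(a), list(lab), "m01")
  expect_false(any(ds@pixelIndex[, 1] == 9L & ds@pixelIndex[, 2] == 11L))
  # and NaN in probability maps
  m <- mlpModel(c(nBands(a), 4, 1), seed = 1L)
  pm <- predictMap(m, a)
  expect_true(is.na(cubeValues(pm)[10, 12]))
})
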