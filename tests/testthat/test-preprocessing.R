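test_that("SNV matches the by-hand case and is idempotent and affine-invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))          # mean 2, sample SD 1
  set.seed(30)
  for (k in 1:200) {
    x <- rnorm(14, mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    z <- snv(x)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
    expect_equal(snv(z), z, tolerance = 1e-12)                 # idempotence
    a <- runif(1, 0.1, 10); b <- runif(1, -20, 20)
    expect_equal(snv(a * x + b), z, tolerance = 1e-9)          # affine invariance
  }
})

test_that("SNV rejects degenerate input", {
  expect_error(snv(rep(2, 14)), "degenerate")
  expect_error(snv(c(1, NaN, 3)), "finite")
  expect_error(snv(3), "at least 2")
})

test_that("population-SD convention differs by the expected factor", {
  x <- c(1, 2, 3, 7)
  expect_equal(snv(x, sdType = "population"),
               snv(x) * sqrt(length(x) / (length(x) - 1)))
})

test_that("dataset assembly preserves counts, order and SNV invariants", {
  set.seed(31)
  H <- 10L; W <- 12L; B <- 5L
  v <- array(runif(H * W * B, 0.1, 1.5), c(H, W, B))
  cube <- absCube(v)
  lab <- matrix(0L, H, W)
  lab[2:4, 2:6] <- 1L      # 15 normal
  lab[7:8, 8:10] <- 2L     # 6 tumor
  ds <- buildDataset(list(cube), list(lab), "m01")
  expect_equal(length(ds), 21L)
  expect_equal(sum(ds@y == 1L), 6L)
  expect_true(max(abs(rowMeans(ds@X))) < 1e-10)
  expect_true(max(abs(apply(ds@X, 1, sd) - 1)) < 1e-10)
  # deterministic ordering by (animal, row, col)
  o <- order(ds@animalId, ds@pixelIndex[, 1], ds@pixelIndex[, 2])
  expect_identical(o, seq_len(length(ds)))
  # same content from permuted inputs
  ds2 <- buildDataset(list(cube, cube), list(lab * 0L, lab), c("m02", "m01"))
  expect_error(buildDataset(list(cube), list(lab * 0L), "m01"), "zero labeled")
  expect_equal(ds2@X[ds2@animalId == "m01", ], ds@X)
})

test_that("invalid and constant-spectrum pixels never enter a dataset", {
  H <- 6L; W <- 6L; B <- 4L
  v <- array(runif(H * W * B, 0.2, 1), c(H, W, B))
  v[2, 2, ] <- 0.7                      # constant spectrum: SNV undefined
  valid <- matrix(TRUE, H, W); valid[3, 3] <- FALSE
  v[3, 3, ] <- NaN
  cube <- spectralCube(v, seq(1000, by = 100, length.out = B), valid = valid,
                       space = "absorbance")
  lab <- matrix(1L, H, W)
  ds <- buildDataset(list(cube), list(lab), "m01")
  expect_equal(length(ds), H * W - 2L)
})

test_that("phantom class-mean SNV spectra separate exactly at the delta bands", {
  # artifact-free phantoms so the generator's spectral contract is isolated
  # from halation/shadow nuisance patches
  sp <- tinySpec(nAnimals = 2L, tumorContrast = 3, halationProb = 0,
                 shadowProb = 0)
  co <- generateCohort(sp)
  cubes <- list(); masks <- list(); ids <- character(0)
  for (el in co) {
    a <- computeAbsorbance(registerBundle(el$post$bundle,
                                          registrationFromTruth(el$post$truth$bandScales)))
    cubes <- c(cubes, list(a)); masks <- c(masks, list(el$post$truth$labels))
    ids <- c(ids, el$animalId)
  }
  ds <- buildDataset(cubes, masks, ids)
  mm <- meanClassSpectra(ds)
  expect_equal(nrow(mm), 4)             # 2 animals x 2 classes
  expect_true(all(mm$present))
  wlCols <- grep("^wl_", names(mm))
  # closed-form oracle: SNV of the two endmember absorbance spectra
  An <- -log10(sp@endmemberNormal); At <- -log10(sp@endmemberTumor)
  theory <- (At - mean(At)) / sd(At) - (An - mean(An)) / sd(An)
  for (id in unique(mm$animal_id)) {
    tum <- as.numeric(mm[mm$animal_id == id & mm$class == "tumor", wlCols])
    nor <- as.numeric(mm[mm$animal_id == id & mm$class == "normal", wlCols])
    diff <- tum - nor
    top3 <- sort(order(diff, decreasing = TRUE)[1:3])
    expect_equal(sp@wavelengths[top3], sp@deltaBands)
    expect_lt(max(abs(diff - theory)), 0.03)
  }
})

test_that("a missing class is flagged absent, not fabricated", {
  set.seed(33)
  v <- array(runif(4 * 4 * 3, 0.2, 1), c(4, 4, 3))
  lab <- matrix(1L, 4, 4)               # normal only
  ds <- buildDataset(list(absCube(v)), list(lab), "m01")
  mm <- meanClassSpectra(ds)
  expect_false(mm$present[mm$class == "tumor"])
  expect_true(all(is.na(mm[mm$class == "tumor", grep("^wl_", names(mm))])))
  rowOne <- matrix(snv(v[1, 1, ]), 1)
  ds1 <- new("PixelDataset", X = rowOne[rep(1, 3), ], y = rep(0L, 3),
             animalId = rep("a", 3), pixelIndex = cbind(0:2, 0L),
             wavelengths = c(1, 2, 3))
  m1 <- meanClassSpectra(ds1)
  expect_equal(as.numeric(m1[m1$class == "normal", grep("^wl_", names(m1))]),
               as.numeric(rowOne))      # mean of identical rows is the row
})
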