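test_that("confusion counting covers the four groups and ignores the unlabeled", {
  lab <- matrix(0L, 10, 10)
  lab[1:2, 1:5] <- 2L     # 10 tumor px
  lab[3:10, 1:10] <- 1L   # and a large normal region; row 1 cols 6:10 unlabeled
  lab[2, 6:10] <- 1L
  ntum <- sum(lab == 2L); nnorm <- sum(lab == 1L)
  expect_equal(c(ntum, nnorm), c(10, 85))
  perfect <- lab == 2L
  cc <- confusionCounts(perfect, lab)
  expect_equal(unname(cc), c(ntum, 0L, 0L, nnorm))
  allNormal <- matrix(FALSE, 10, 10)
  cc2 <- confusionCounts(allNormal, lab)
  expect_equal(unname(cc2), c(0L, ntum, 0L, nnorm))
  expect_error(confusionCounts(allNormal, matrix(0L, 10, 10)), "no labeled")
  expect_error(confusionCounts(matrix(FALSE, 2, 2), lab), "shapes")
  # unscored pixels are excluded from the counts
  attr(perfect, "unscored") <- matrix(FALSE, 10, 10)
  attr(perfect, "unscored")[1, 1] <- TRUE
  expect_equal(unname(confusionCounts(perfect, lab))[1], ntum - 1L)
})

test_that("specificity, sensitivity and accuracy follow their defining ratios", {
  m <- classificationMetrics(c(TP = 1, FN = 0, FP = 0, TN = 1))
  expect_equal(c(m$specificity_pct, m$sensitivity_pct, m$accuracy_pct),
               c(100, 100, 100))
  m2 <- classificationMetrics(c(TP = 0, FN = 1, FP = 0, TN = 1))
  expect_equal(c(m2$specificity_pct, m2$sensitivity_pct, m2$accuracy_pct),
               c(100, 0, 50))
  expect_error(classificationMetrics(c(TP = 0, FN = 0, FP = 0, TN = 0)),
               "all-zero")
  # empty tumor class: sensitivity reported absent
  m3 <- classificationMetrics(c(TP = 0, FN = 0, FP = 2, TN = 8))
  expect_true(is.na(m3$sensitivity_pct))
  expect_equal(m3$accuracy_pct, 80)
})

test_that("pooling sums counts; accuracy sits between the class rates", {
  a <- classificationMetrics(c(TP = 5, FN = 5, FP = 10, TN = 80), "a")
  b <- classificationMetrics(c(TP = 20, FN = 5, FP = 1, TN = 24), "b")
  p <- poolMetrics(rbind(a, b))
  expect_equal(p$TP, 25); expect_equal(p$TN, 104)
  expect_equal(p$tumor_px, 35); expect_equal(p$normal_px, 115)
  expect_equal(poolMetrics(a)$accuracy_pct, a$accuracy_pct)
  wmin <- min(p$specificity_pct, p$sensitivity_pct)
  wmax <- max(p$specificity_pct, p$sensitivity_pct)
  expect_gte(p$accuracy_pct, wmin)
  expect_lte(p$accuracy_pct, wmax)
})

test_that("LOOCV on a 2-animal cohort trains on exactly the other animal", {
  sp <- tinySpec(nAnimals = 2L)
  co <- generateCohort(sp)
  cfg <- trainConfig(epochs = 2L, batchSize = 128L, dropoutRate = 0, seed = 9L)
  res <- runLOOCV(co, layerSizes = c(4L), config = cfg)
  expect_equal(nrow(res$reports), 3)
  expect_equal(res$reports$animal_id, c("m01", "m02", "total"))
  expect_setequal(names(res$maps), c("m01", "m02"))
  expect_equal(res$reports$TP[3], sum(res$reports$TP[1:2]))
  expect_equal(res$reports$tumor_px[3], sum(res$reports$tumor_px[1:2]))
  expect_error(runLOOCV(co[1], config = cfg), "at least 2")
})

test_that("the held-out animal's labels cannot influence its own prediction", {
  sp <- tinySpec(nAnimals = 2L)
  co <- generateCohort(sp)
  cfg <- trainConfig(epochs = 2L, batchSize = 128L, dropoutRate = 0, seed = 10L)
  res <- runLOOCV(co, layerSizes = c(4L), config = cfg)
  # corrupt animal 1's own labels: its probability map must be unchanged
  co2 <- co
  lab <- co2[[1]]$post$truth$labels
  lab[lab == 1L] <- 2L
  co2[[1]]$post$truth$labels <- lab
  res2 <- runLOOCV(co2, layerSizes = c(4L), config = cfg)
  expect_identical(cubeValues(res$maps[["m01"]]), cubeValues(res2$maps[["m01"]]))
})

test_that("an animal without tumor labels warns and is scored for specificity", {
  sp <- tinySpec(nAnimals = 3L)
  co <- generateCohort(sp)
  lab <- co[[3]]$post$truth$labels
  lab[lab == 2L] <- 0L
  co[[3]]$post$truth$labels <- lab
  co[[3]]$post$bundle@labels <- lab
  cfg <- trainConfig(epochs = 2L, batchSize = 128L, dropoutRate = 0, seed = 11L)
  expect_warning(res <- runLOOCV(co, layerSizes = c(4L), config = cfg),
                 "sensitivity undefined")
  r3 <- res$reports[res$reports$animal_id == "m03", ]
  expect_true(is.na(r3$sensitivity_pct))
  expect_false(is.na(r3$specificity_pct))
})
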