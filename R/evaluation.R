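#' @include mlp.R
NULL

#' Confusion counts over labeled, scored pixels
#'
#' Classifies pixels into the four groups — tumor predicted as tumor (TP),
#' tumor as normal (FN), normal as tumor (FP), normal as normal (TN) —
#' counting only pixels that carry a class label and were actually scored;
#' unlabeled, invalid and unscored pixels are ignored.
#'
#' @param binaryMap logical matrix (TRUE = predicted tumor), e.g. from
#'   \code{\link{binarize}}; its "unscored" attribute, when present,
#'   excludes those pixels.
#' @param labels integer matrix, 0 = unlabeled, 1 = normal, 2 = tumor.
#' @return named integer vector c(TP, FN, FP, TN).
#' @export
confusionCounts <- function(binaryMap, labels) {
  if (!identical(dim(binaryMap), dim(labels)))
    stop("prediction and label shapes must agree")
  scored <- labels > 0L
  uns <- attr(binaryMap, "unscored")
  if (!is.null(uns)) scored <- scored & !uns
  if (!any(scored)) stop("no labeled scored pixels to count")
  pred <- binaryMap[scored]
  truth <- labels[scored] == 2L
  c(TP = sum(truth & pred), FN = sum(truth & !pred),
    FP = sum(!truth & pred), TN = sum(!truth & !pred))
}

#' Specificity, sensitivity and accuracy from confusion counts
#'
#' Specificity = TN/(FP+TN) x 100, Sensitivity = TP/(TP+FN) x 100,
#' Accuracy = (TP+TN)/(TP+TN+FP+FN) x 100.  Percentages are reported at
#' full precision (round for display); a metric with an empty denominator
#' is reported absent (NA).
#'
#' @param counts named vector with TP, FN, FP, TN.
#' @param animalId row label (default "total").
#' @return one-row data.frame: animal_id, tumor_px, normal_px,
#'   specificity_pct, sensitivity_pct, accuracy_pct, TP, FN, FP, TN.
#' @examples
#' classificationMetrics(c(TP = 2629, FN = 2287, FP = 10212, TN = 87292))
#' @export
classificationMetrics <- function(counts, animalId = "total") {
  cts <- as.numeric(counts[c("TP", "FN", "FP", "TN")])
  if (anyNA(cts)) stop("counts must provide TP, FN, FP and TN")
  if (sum(cts) == 0) stop("all-zero confusion counts")
  TP <- cts[1]; FN <- cts[2]; FP <- cts[3]; TN <- cts[4]
  data.frame(animal_id = animalId,
             tumor_px = TP + FN, normal_px = FP + TN,
             specificity_pct = if (FP + TN > 0) TN / (FP + TN) * 100 else NA_real_,
             sensitivity_pct = if (TP + FN > 0) TP / (TP + FN) * 100 else NA_real_,
             accuracy_pct = (TP + TN) / (TP + TN + FP + FN) * 100,
             TP = TP, FN = FN, FP = FP, TN = TN)
}

#' Pool per-animal reports into a total row
#'
#' Sums the confusion counts across animals and recomputes the metrics
#' from the pooled counts — never by averaging per-animal percentages,
#' which differs whenever class sizes vary across animals.
#'
#' @param reports data.frame of per-animal rows from
#'   \code{\link{classificationMetrics}}.
#' @return one-row data.frame labeled "total".
#' @export
poolMetrics <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  classificationMetrics(c(TP = sum(reports$TP), FN = sum(reports$FN),
                          FP = sum(reports$FP), TN = sum(reports$TN)),
                        animalId = "total")
}

## Prepare one animal: register the pre/post bundles, calibrate to
## absorbance, and return cubes + label masks.  `registration` selects the
## source of the per-band parameters.
prepareAnimal <- function(animal, registration = c("truth", "estimate", "none")) {
  registration <- match.arg(registration)
  regFor <- function(gen) {
    switch(registration,
      truth = registrationFromTruth(gen$truth$bandScales),
      estimate = estimateRegistration(gen$bundle@raw),
      none = identityRegistration(gen$bundle@raw))
  }
  prep <- function(gen) {
    reg <- regFor(gen)
    bundle <- registerBundle(gen$bundle, reg)
    list(abs = computeAbsorbance(bundle), labels = gen$truth$labels)
  }
  list(pre = prep(animal$pre), post = prep(animal$post))
}

#' Leave-one-animal-out cross-validation over a cohort
#'
#' For each held-out animal, trains a fresh model (independent seeded
#' initialization derived from the global seed and the held-out id) on the
#' other animals' pixel datasets — normal teaching rows from pre-implant
#' images, tumor teaching rows from the labeled tumor regions of
#' post-implant images — then predicts the held-out animal's post-implant
#' probability map and scores its labeled pixels only.  The unit of
#' cross-validation is the animal, never the pixel, so no animal's pixels
#' ever inform its own prediction.
#'
#' @param cohort list from \code{\link{generateCohort}} (or the same shape
#'   built from real bundles + ground-truth masks).
#' @param layerSizes hidden architecture for \code{\link{trainMLP}}.
#' @param config a \code{\link{trainConfig}}; each fold derives its own
#'   seed from \code{config$seed} and the held-out animal id.
#' @param cutoff tumor cutoff for binarization (default 0.60).
#' @param registration "truth" (use generator drift scales), "estimate"
#'   (recover them from the raw cubes), or "none".
#' @return list: \code{reports} (per-animal rows + pooled "total" row),
#'   \code{maps} (named list of \linkS4class{ProbabilityMap}s),
#'   \code{lossHistories}.
#' @export
runLOOCV <- function(cohort, layerSizes = c(64L, 32L), config = trainConfig(),
                     cutoff = 0.60, registration = "truth") {
  if (length(cohort) < 2) stop("leave-one-animal-out needs at least 2 animals")
  prepped <- lapply(cohort, prepareAnimal, registration = registration)
  names(prepped) <- vapply(cohort, `[[`, "", "animalId")
  ids <- names(prepped)
  teachingCubes <- function(keep) {
    cubes <- list(); masks <- list(); aids <- character(0)
    for (id in keep) {
      pr <- prepped[[id]]
      ## normal rows from the pre-implant session
      preMask <- pr$pre$labels; preMask[preMask == 2L] <- 0L
      ## tumor rows from the post-implant session
      postMask <- pr$post$labels; postMask[postMask == 1L] <- 0L
      cubes <- c(cubes, list(pr$pre$abs, pr$post$abs))
      masks <- c(masks, list(preMask, postMask))
      aids <- c(aids, id, id)
    }
    buildDataset(cubes, masks, aids)
  }
  reports <- NULL; maps <- list(); lossHistories <- list()
  for (id in ids) {
    train <- teachingCubes(setdiff(ids, id))
    stopifnot(!id %in% train@animalId)   # leave-one-animal-out hygiene
    foldConfig <- config
    foldConfig$seed <- deriveSeed(config$seed, "fold", id)
    if (sum(train@y == 1L) == 0)
      stop("teaching set has no tumor pixels; check post-implant labels")
    fit <- trainMLP(train, layerSizes = layerSizes, config = foldConfig)
    pm <- predictMap(fit$model, prepped[[id]]$post$abs, cutoff = cutoff)
    heldLabels <- prepped[[id]]$post$labels
    if (sum(heldLabels == 2L) == 0)
      warning(sprintf("animal %s has no tumor labels: sensitivity undefined, %s",
                      id, "scored for specificity only"))
    cc <- confusionCounts(binarize(pm), heldLabels)
    reports <- rbind(reports, classificationMetrics(cc, animalId = id))
    maps[[id]] <- pm
    lossHistories[[id]] <- fit$lossHistory
  }
  reports <- rbind(reports, poolMetrics(reports))
  rownames(reports) <- NULL
  list(reports = reports, maps = maps, lossHistories = lossHistories)
}
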