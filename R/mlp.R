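#' @include AllClasses.R
NULL

sigmoidFn <- function(z) 1 / (1 + exp(-z))

actFn <- function(z, kind) {
  switch(kind, relu = pmax(z, 0), sigmoid = sigmoidFn(z), identity = z)
}
actGrad <- function(z, a, kind) {
  switch(kind, relu = (z > 0) * 1, sigmoid = a * (1 - a),
         identity = array(1, dim = dim(z)))
}

#' Initialize an MLP model
#'
#' He-style Gaussian initialization (SD sqrt(2 / fan-in)) for the weights,
#' zero biases.  The output layer is a single sigmoid unit emitting the
#' tumor probability.
#'
#' @param layerSizes integer vector, input size through hidden sizes; a
#'   trailing 1 is appended if absent.
#' @param hiddenActivation "relu" (default), "sigmoid", or "identity"
#'   (diagnostic use).
#' @param dropoutRate dropout probability for training mode, applied to
#'   every layer's output except the final layer (default 0.5).
#' @param seed initialization seed.
#' @return an \linkS4class{MLPModel}.
#' @export
mlpModel <- function(layerSizes, hiddenActivation = c("relu", "sigmoid", "identity"),
                     dropoutRate = 0.5, seed = 1L) {
  hiddenActivation <- match.arg(hiddenActivation)
  layerSizes <- as.integer(layerSizes)
  if (layerSizes[length(layerSizes)] != 1L) layerSizes <- c(layerSizes, 1L)
  L <- length(layerSizes)
  withSeed(seed, {
    W <- lapply(seq_len(L - 1), function(l)
      matrix(rnorm(layerSizes[l] * layerSizes[l + 1]) * sqrt(2 / layerSizes[l]),
             layerSizes[l], layerSizes[l + 1]))
    b <- lapply(seq_len(L - 1), function(l) numeric(layerSizes[l + 1]))
    new("MLPModel", layerSizes = layerSizes, weights = W, biases = b,
        hiddenActivation = hiddenActivation, dropoutRate = dropoutRate,
        seed = as.integer(seed))
  })
}

## Forward pass over a batch.  X is n x d.  In training mode inverted
## dropout masks (kept units scaled by 1/(1-p)) are applied to the input
## and every hidden layer's output — all layers except the final one.
## `masks` may inject fixed dropout masks (list of n x n_l 0/1 matrices,
## one per non-final layer including the input); when NULL and trainMode,
## masks are drawn from the current RNG stream.
mlpForwardFull <- function(model, X, trainMode = FALSE, masks = NULL,
                           rawLogit = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model@layerSizes[1])
    stop(sprintf("input has %d feature(s); model expects %d", ncol(X),
                 model@layerSizes[1]))
  L <- length(model@layerSizes)
  p <- model@dropoutRate
  useDrop <- trainMode && p > 0
  a <- X
  as <- vector("list", L); zs <- vector("list", L)
  usedMasks <- vector("list", L - 1)
  dropIt <- function(a, l) {
    if (!useDrop) return(a)
    m <- if (!is.null(masks)) masks[[l]] else
      matrix(runif(length(a)) >= p, nrow(a), ncol(a)) * 1
    usedMasks[[l]] <<- m
    a * m / (1 - p)
  }
  a <- dropIt(a, 1L)
  as[[1]] <- a
  for (l in seq_len(L - 1)) {
    z <- a %*% model@weights[[l]] + matrix(model@biases[[l]], nrow(a),
                                           model@layerSizes[l + 1], byrow = TRUE)
    zs[[l + 1]] <- z
    if (l < L - 1) {
      a <- actFn(z, model@hiddenActivation)
      a <- dropIt(a, l + 1L)
    } else {
      a <- if (rawLogit) z else sigmoidFn(z)
    }
    as[[l + 1]] <- a
  }
  list(out = a[, 1], as = as, zs = zs, masks = usedMasks)
}

#' Forward pass: tumor probability for one or more spectra
#'
#' Affine map then activation per layer (ReLU or sigmoid hidden units,
#' sigmoid output).  In training mode, inverted dropout is applied to
#' every layer's output except the final layer; in evaluation mode no
#' dropout and no rescaling is applied.
#'
#' @param model an \linkS4class{MLPModel}.
#' @param x numeric vector (one spectrum) or n x B matrix.
#' @param trainMode apply dropout (default FALSE).
#' @return numeric vector of probabilities in (0, 1).
#' @export
mlpForward <- function(model, x, trainMode = FALSE) {
  mlpForwardFull(model, x, trainMode = trainMode)$out
}

## Mean binary cross-entropy and its gradients w.r.t. all weights/biases,
## with dropout masks fixed per forward pass.  `sampleWeights` rescales
## per-example losses (class balancing).
mlpGradients <- function(model, X, y, trainMode = FALSE, masks = NULL,
                         sampleWeights = NULL) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  n <- nrow(X)
  if (n == 0) stop("empty batch")
  fw <- mlpForwardFull(model, X, trainMode = trainMode, masks = masks)
  p <- fw$out
  eps <- 1e-12
  w <- if (is.null(sampleWeights)) rep(1, n) else sampleWeights
  loss <- -mean(w * (y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps))))
  if (!is.finite(loss)) stop("non-finite training loss: diverged or bad input")
  L <- length(model@layerSizes)
  dW <- vector("list", L - 1); db <- vector("list", L - 1)
  ## sigmoid + BCE: dE/dz_L = (p - y) * w / n
  delta <- matrix((p - y) * w / n, n, 1)
  for (l in (L - 1):1) {
    dW[[l]] <- crossprod(fw$as[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) {
      da <- delta %*% t(model@weights[[l]])
      if (!is.null(fw$masks[[l]]))                      # dropout on layer l output
        da <- da * fw$masks[[l]] / (1 - model@dropoutRate)
      aPre <- actFn(fw$zs[[l]], model@hiddenActivation)  # pre-dropout activation
      delta <- da * actGrad(fw$zs[[l]], aPre, model@hiddenActivation)
    }
  }
  list(loss = loss, dW = dW, db = db, prob = p)
}

#' Training configuration
#'
#' Adam hyperparameters, epochs, batching, dropout and loss options for
#' \code{\link{trainMLP}}.  The loss is binary cross-entropy, the standard
#' pairing with a sigmoid probability output.
#'
#' @param learningRate Adam step size (default 1e-3).
#' @param epochs training epochs (default 100).
#' @param batchSize minibatch size (default 256).
#' @param dropoutRate dropout probability (default 0.5).
#' @param adamBetas first/second moment decay (default c(0.9, 0.999)).
#' @param adamEpsilon Adam denominator floor (default 1e-8).
#' @param classWeighting "none" (default; mirrors the naturally imbalanced
#'   normal:tumor regime) or "balanced".
#' @param seed seed for shuffling, initialization and dropout.
#' @return list of class "trainConfig".
#' @export
trainConfig <- function(learningRate = 1e-3, epochs = 100L, batchSize = 256L,
                        dropoutRate = 0.5, adamBetas = c(0.9, 0.999),
                        adamEpsilon = 1e-8,
                        classWeighting = c("none", "balanced"), seed = 1L) {
  stopifnot(learningRate > 0, dropoutRate >= 0, dropoutRate < 1)
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), dropoutRate = dropoutRate,
                 adamBetas = adamBetas, adamEpsilon = adamEpsilon,
                 classWeighting = match.arg(classWeighting),
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Train an MLP on a pixel dataset
#'
#' Minibatch Adam (bias-corrected moment estimates) on the mean binary
#' cross-entropy, with seeded shuffling, initialization and dropout so a
#' given (dataset, configuration, seed) triple always yields identical
#' weights.
#'
#' @param dataset a \linkS4class{PixelDataset} (or list with X and y)
#'   containing both classes.
#' @param layerSizes hidden architecture; the input size is taken from the
#'   data and a 1-unit sigmoid output is appended (default hidden 64-32).
#' @param config a \code{\link{trainConfig}}.
#' @param hiddenActivation hidden unit type (default "relu").
#' @return list: \code{model} (trained \linkS4class{MLPModel}),
#'   \code{lossHistory} (per-epoch mean training loss).
#' @export
trainMLP <- function(dataset, layerSizes = c(64L, 32L), config = trainConfig(),
                     hiddenActivation = "relu") {
  if (is(dataset, "PixelDataset")) { X <- dataset@X; y <- dataset@y }
  else { X <- dataset$X; y <- dataset$y }
  if (length(unique(y)) < 2)
    stop("training requires both classes in the dataset")
  n <- nrow(X)
  model <- mlpModel(c(ncol(X), layerSizes, 1L),
                    hiddenActivation = hiddenActivation,
                    dropoutRate = config$dropoutRate,
                    seed = deriveSeed(config$seed, "init"))
  sw <- NULL
  if (config$classWeighting == "balanced") {
    tab <- table(factor(y, levels = 0:1))
    sw <- n / (2 * as.numeric(tab[as.character(y)]))
  }
  b1 <- config$adamBetas[1]; b2 <- config$adamBetas[2]
  mW <- lapply(model@weights, function(w) w * 0); vW <- mW
  mB <- lapply(model@biases, function(b) b * 0); vB <- mB
  t <- 0L
  lossHistory <- numeric(config$epochs)
  withSeed(deriveSeed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batchSize - 1L, n)]
        g <- mlpGradients(model, X[idx, , drop = FALSE], y[idx],
                          trainMode = config$dropoutRate > 0,
                          sampleWeights = sw[idx])
        t <- t + 1L
        for (l in seq_along(model@weights)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$dW[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$dW[[l]]^2
          mB[[l]] <- b1 * mB[[l]] + (1 - b1) * g$db[[l]]
          vB[[l]] <- b2 * vB[[l]] + (1 - b2) * g$db[[l]]^2
          mhW <- mW[[l]] / (1 - b1^t); vhW <- vW[[l]] / (1 - b2^t)
          mhB <- mB[[l]] / (1 - b1^t); vhB <- vB[[l]] / (1 - b2^t)
          model@weights[[l]] <- model@weights[[l]] -
            config$learningRate * mhW / (sqrt(vhW) + config$adamEpsilon)
          model@biases[[l]] <- model@biases[[l]] -
            config$learningRate * mhB / (sqrt(vhB) + config$adamEpsilon)
        }
        epochLoss <- epochLoss + g$loss * length(idx)
      }
      lossHistory[epoch] <- epochLoss / n
    }
  })
  list(model = model, lossHistory = lossHistory)
}

#' Per-pixel tumor probability map of an absorbance cube
#'
#' SNV-normalizes every valid pixel's spectrum and runs the model in
#' evaluation mode.  Invalid pixels, and pixels whose spectrum is constant
#' (SNV undefined) or non-finite, are NaN in the map and flagged in the
#' \code{degenerate} attribute rather than classified.
#'
#' @param model a trained \linkS4class{MLPModel}.
#' @param cube a registered absorbance \linkS4class{SpectralCube} whose
#'   band count equals the model input size.
#' @param cutoff cutoff stored with the map (default 0.60).
#' @return a \linkS4class{ProbabilityMap}; attribute "degenerate" marks
#'   valid pixels that could not be scored.
#' @export
predictMap <- function(model, cube, cutoff = 0.60) {
  if (cubeSpace(cube) != "absorbance")
    stop("prediction requires an absorbance cube")
  B <- nBands(cube)
  if (B != model@layerSizes[1])
    stop(sprintf("cube has %d band(s); model expects %d", B, model@layerSizes[1]))
  d <- dim(cube@values)
  X <- matrix(cube@values, d[1] * d[2], B)   # pixels in column-major order
  finite <- rowSums(is.finite(X)) == B
  constant <- finite & apply(X, 1, function(r) if (all(is.finite(r))) sd(r) == 0 else FALSE)
  score <- finite & !constant & as.vector(cube@valid)
  vals <- rep(NaN, d[1] * d[2])
  if (any(score))
    vals[score] <- mlpForward(model, snvRows(X[score, , drop = FALSE]))
  pm <- new("ProbabilityMap", values = matrix(vals, d[1], d[2]), cutoff = cutoff)
  attr(pm, "degenerate") <- matrix(as.vector(cube@valid) & !score, d[1], d[2])
  pm
}

#' Binarize a probability map at its cutoff
#'
#' Tumor where p >= cutoff (boundary inclusive); NaN pixels are not tumor
#' and are flagged unscored.
#'
#' @param probMap a \linkS4class{ProbabilityMap}.
#' @param cutoff override of the stored cutoff, in (0, 1).
#' @return logical H x W matrix (TRUE = tumor) with attribute "unscored".
#' @export
binarize <- function(probMap, cutoff = probMap@cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  v <- probMap@values
  out <- !is.na(v) & v >= cutoff
  attr(out, "unscored") <- is.na(v)
  out
}
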