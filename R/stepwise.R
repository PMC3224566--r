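# Forward stepwise ion ranking with I-2-1 backpropagation networks under
# Monte-Carlo cross-validation: each step scores every remaining candidate
# ion added to the selected set, averaging train/test/validation MSE over
# random 60:20:20 resamples; the candidate with the lowest average test
# error wins the step.

#' Stepwise ANN parameters
#'
#' @param hiddenUnits hidden-layer size (default 2: I-2-1 nets).
#' @param learningRate backpropagation learning rate (default 0.1).
#' @param momentum momentum rate (default 0.5).
#' @param maxEpochs training epoch cap (default 3000).
#' @param windowEpochs early-stopping window: training stops when the
#'   test-partition MSE has not improved by at least `errorThreshold`
#'   within this many epochs (default 1000).
#' @param errorThreshold minimum MSE improvement that resets the window
#'   (default 0.01).
#' @param nResamples Monte-Carlo resamples per model (default 50).
#' @param maxSteps panel length: number of stepwise additions (default 10).
#' @param splitRatio train/test/validation fractions (default 60:20:20).
#' @param seed master seed; the resample splits and weight
#'   initialisations derive from it.
#' @return a `StepwiseParams` (validated list).
#' @export
stepwiseParams <- function(hiddenUnits = 2, learningRate = 0.1,
                           momentum = 0.5, maxEpochs = 3000,
                           windowEpochs = 1000, errorThreshold = 0.01,
                           nResamples = 50, maxSteps = 10,
                           splitRatio = c(0.6, 0.2, 0.2), seed = 1) {
  p <- list(hiddenUnits = as.integer(hiddenUnits),
            learningRate = learningRate, momentum = momentum,
            maxEpochs = as.integer(maxEpochs),
            windowEpochs = as.integer(windowEpochs),
            errorThreshold = errorThreshold,
            nResamples = as.integer(nResamples),
            maxSteps = as.integer(maxSteps),
            splitRatio = as.numeric(splitRatio), seed = as.integer(seed))
  stopIfNot(abs(sum(p$splitRatio) - 1) < 1e-9,
            "splitRatio must sum to 1")
  stopIfNot(all(c(p$hiddenUnits, p$maxEpochs, p$windowEpochs,
                  p$nResamples, p$maxSteps) > 0),
            "all counts must be positive")
  class(p) <- c("StepwiseParams", "list")
  p
}

#' Stratified Monte-Carlo train/test/validation split
#'
#' Global partition sizes follow round-to-nearest with the remainder going
#' to the validation partition (69 samples at 60:20:20 give 41/14/14; 111
#' give 67/22/22); each partition is then apportioned across the two
#' classes by largest remainder so no class can vanish from a partition.
#'
#' @param labels class labels of the samples to split.
#' @param ratio three fractions summing to 1 (default 60:20:20).
#' @param seed split seed.
#' @return list with disjoint, exhaustive index vectors `train`, `test`,
#'   `valid`.
#' @export
mccvSplit <- function(labels, ratio = c(0.6, 0.2, 0.2), seed = 1) {
  n <- length(labels)
  stopIfNot(n >= 5, "need at least 5 samples to split")
  nTrain <- round(ratio[1] * n)
  nTest <- round(ratio[2] * n)
  nValid <- n - nTrain - nTest
  cls <- unique(labels)
  counts <- vapply(cls, function(c) sum(labels == c), 0L)
  trainPer <- apportion(nTrain, counts)
  testPer <- apportion(nTest, counts * (nTest / n))  # weights proportional
  # guard: test apportionment must not exceed what train left over
  testPer <- pmin(testPer, counts - trainPer)
  short <- nTest - sum(testPer)
  if (short > 0) {
    room <- counts - trainPer - testPer
    for (k in order(room, decreasing = TRUE)) {
      add <- min(short, room[k]); testPer[k] <- testPer[k] + add
      short <- short - add
      if (short == 0) break
    }
  }
  validPer <- counts - trainPer - testPer
  if (any(trainPer == 0) || any(testPer == 0) || any(validPer == 0))
    stop("stratification error: a class would be absent from a partition")
  train <- test <- valid <- integer(0)
  withSeed(seed, {
    for (k in seq_along(cls)) {
      idx <- sample(which(labels == cls[k]))
      train <- c(train, idx[seq_len(trainPer[k])])
      test <- c(test, idx[trainPer[k] + seq_len(testPer[k])])
      valid <- c(valid, idx[trainPer[k] + testPer[k] + seq_len(validPer[k])])
    }
  })
  list(train = sort(train), test = sort(test), valid = sort(valid))
}

#' Train one I-2-1 backpropagation network
#'
#' Weights start uniform in [-0.5, 0.5]; training is per-pattern
#' (sequential) gradient descent on MSE with momentum, pattern order
#' reshuffled every epoch; the output unit is tanh rescaled to [0, 1] via
#' (tanh+1)/2 against \{0, 1\} targets.  Early stopping keeps the weights
#' with the best test-partition MSE (see [stepwiseParams()]).
#'
#' @param X standardized samples x features training matrix.
#' @param y integer \{0, 1\} targets.
#' @param Xtest,ytest test partition used for early stopping.
#' @param params a [stepwiseParams()].
#' @param seed training seed (weight init and pattern shuffles).
#' @return an `AnnModel` list: `W1` ((I+1) x H weight matrix, bias row
#'   last), `W2` (H+1 weights, bias last), `epochs`, `trainMse`, `testMse`.
#' @export
trainAnn <- function(X, y, Xtest, ytest, params = stepwiseParams(),
                     seed = params$seed) {
  X <- as.matrix(X); Xtest <- as.matrix(Xtest)
  fit <- ann_train_cpp(X, as.numeric(y), Xtest, as.numeric(ytest),
                       params$hiddenUnits, params$learningRate,
                       params$momentum, params$maxEpochs,
                       params$windowEpochs, params$errorThreshold,
                       as.integer(seed))
  structure(list(W1 = fit$W1, W2 = fit$W2, epochs = fit$epochs,
                 trainMse = fit$train_mse, testMse = fit$test_mse),
            class = c("AnnModel", "list"))
}

#' Predict with a trained network
#'
#' @param model an `AnnModel` from [trainAnn()].
#' @param X standardized samples x features matrix (same features, same
#'   scaling as training).
#' @return numeric outputs in [0, 1].
#' @export
predictAnn <- function(model, X) {
  ann_predict_cpp(model$W1, model$W2, as.matrix(X))
}

# Shared split/seed schedule for one ranking experiment: the same
# resamples are reused for every candidate so candidates are compared on
# identical partitions (and the ranking cannot depend on column order).
.mccvSchedule <- function(labels, params) {
  seeds <- deriveSeeds(params$seed, params$nResamples)
  list(splits = lapply(seeds, function(s)
    mccvSplit(labels, params$splitRatio, seed = s)),
    seeds = seeds)
}

.scoreOnSchedule <- function(X, y01, schedule, params) {
  acc <- c(train = 0, test = 0, valid = 0)
  for (r in seq_along(schedule$splits)) {
    sp <- schedule$splits[[r]]
    st <- zscoreStats(X[sp$train, , drop = FALSE])
    Xs <- zscoreApply(X, st)
    m <- trainAnn(Xs[sp$train, , drop = FALSE], y01[sp$train],
                  Xs[sp$test, , drop = FALSE], y01[sp$test],
                  params, seed = schedule$seeds[r])
    mseOf <- function(idx) mean((predictAnn(m, Xs[idx, , drop = FALSE]) -
                                   y01[idx])^2)
    acc <- acc + c(mseOf(sp$train), mseOf(sp$test), mseOf(sp$valid))
  }
  acc / length(schedule$splits)
}

#' Score a feature set by Monte-Carlo cross-validated ANN error
#'
#' Trains one network per resample on the given features and returns the
#' average MSE on the train, test and validation partitions.
#'
#' @param table a [PeakTable-class] with binary labels.
#' @param features feature indices (into the table's peaks) to use.
#' @param params a [stepwiseParams()].
#' @return named numeric vector `c(train=, test=, valid=)`.
#' @export
scoreFeatureSet <- function(table, features, params = stepwiseParams()) {
  X <- featureMatrix(table)[, features, drop = FALSE]
  cn <- inferClassNames(classLabels(table))
  y01 <- codeLabels(classLabels(table), cn)
  schedule <- .mccvSchedule(classLabels(table), params)
  .scoreOnSchedule(X, y01, schedule, params)
}

#' Forward stepwise ion ranking
#'
#' Step 1 scores every peak alone with 1-2-1 networks; the peak with the
#' lowest average test error takes rank 1 (ties: lower m/z).  Step k adds
#' each remaining candidate to the selected set and scores k-2-1 networks;
#' the procedure repeats to `maxSteps` ions.  All candidates within an
#' experiment share the same Monte-Carlo resamples and training seeds, so
#' the ranking is invariant to the order of the peak columns.
#'
#' @param table a [PeakTable-class] with binary labels and at least
#'   `maxSteps` peaks (fewer peaks yield a truncated panel with a warning).
#' @param params a [stepwiseParams()].
#' @return a `RankedPanel` `data.frame`: `rank`, `ion` (label m/z),
#'   `startMz`, `endMz` (when available), `avgTrainError`, `avgTestError`,
#'   `avgValidError`; attribute `"featureIndices"` holds the selected
#'   column indices in rank order.
#' @export
stepwiseRank <- function(table, params = stepwiseParams()) {
  X <- featureMatrix(table)
  cn <- inferClassNames(classLabels(table))
  y01 <- codeLabels(classLabels(table), cn)
  info <- peakInfo(table)
  p <- ncol(X)
  steps <- params$maxSteps
  if (p < steps) {
    warning("only ", p, " peaks available; panel truncated to ", p, " ions")
    steps <- p
  }
  schedule <- .mccvSchedule(classLabels(table), params)
  selected <- integer(0)
  rows <- vector("list", steps)
  for (step in seq_len(steps)) {
    remaining <- setdiff(seq_len(p), selected)   # ascending m/z order
    errs <- vapply(remaining, function(cand)
      .scoreOnSchedule(X[, c(selected, cand), drop = FALSE], y01,
                       schedule, params),
      numeric(3))
    best <- remaining[which.min(errs["test", ])]  # first min = lower m/z
    selected <- c(selected, best)
    rows[[step]] <- data.frame(
      rank = step, ion = info$labelMz[best],
      startMz = if ("startMz" %in% names(info)) info$startMz[best] else NA,
      endMz = if ("endMz" %in% names(info)) info$endMz[best] else NA,
      avgTrainError = errs["train", which(remaining == best)],
      avgTestError = errs["test", which(remaining == best)],
      avgValidError = errs["valid", which(remaining == best)])
  }
  panel <- do.call(rbind, rows)
  attr(panel, "featureIndices") <- selected
  class(panel) <- c("RankedPanel", "data.frame")
  panel
}

#' Fit the final sub-model ensemble on a ranked panel
#'
#' Trains one network per Monte-Carlo resample on the full panel (the
#' classical setting uses 50 resamples) and keeps, for each sub-model, the
#' weights and the train-partition scaling statistics needed to classify
#' blind samples later.
#'
#' @param table the training [PeakTable-class] the panel was ranked on.
#' @param panel a `RankedPanel` from [stepwiseRank()].
#' @param params a [stepwiseParams()].
#' @return an `AnnEnsemble` list: `models` (one per resample, each with
#'   `W1`, `W2`, `center`, `scale`), `featureIndices`, `featureMz`,
#'   `classNames`, `params`.
#' @export
fitFinalEnsemble <- function(table, panel, params = stepwiseParams()) {
  features <- attr(panel, "featureIndices")
  stopIfNot(length(features) > 0, "panel is empty")
  X <- featureMatrix(table)[, features, drop = FALSE]
  cn <- inferClassNames(classLabels(table))
  y01 <- codeLabels(classLabels(table), cn)
  schedule <- .mccvSchedule(classLabels(table), params)
  models <- lapply(seq_along(schedule$splits), function(r) {
    sp <- schedule$splits[[r]]
    st <- zscoreStats(X[sp$train, , drop = FALSE])
    Xs <- zscoreApply(X, st)
    m <- trainAnn(Xs[sp$train, , drop = FALSE], y01[sp$train],
                  Xs[sp$test, , drop = FALSE], y01[sp$test],
                  params, seed = schedule$seeds[r])
    m$center <- st$center; m$scale <- st$scale
    m
  })
  structure(list(models = models, featureIndices = features,
                 featureMz = panel$ion, classNames = cn, params = params),
            class = c("AnnEnsemble", "list"))
}
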