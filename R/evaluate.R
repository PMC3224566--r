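# Blind-set evaluation: stratified 70:30 train/blind split, ensemble
# voting with 95% CI half-widths, per-class TPR/FPR and ROC/AUC by
# threshold sweep.

#' Stratified train/blind split
#'
#' Shuffles within each class and assigns `round(ratio * n_c)` samples per
#' class to the training side, the remainder to the blind side (99 samples
#' at 70:30 give a 30-sample blind set; 158 give 47).  The blind side must
#' never touch any fitting.
#'
#' @param x a [PeakTable-class], or a character vector of class labels.
#' @param ratio training fraction in (0, 1), default 0.7.
#' @param seed split seed.
#' @return for a `PeakTable`: list with `train` and `blind` tables plus
#'   `trainIdx`/`blindIdx`; for labels: the index list only.
#' @export
splitTrainBlind <- function(x, ratio = 0.7, seed = 1) {
  stopIfNot(ratio > 0 && ratio < 1, "ratio must lie in (0, 1)")
  labels <- if (is(x, "PeakTable")) classLabels(x) else x
  cls <- unique(labels)
  stopIfNot(length(cls) == 2, "both classes must be present")
  train <- blind <- integer(0)
  withSeed(seed, {
    for (c in cls) {
      idx <- sample(which(labels == c))
      nTr <- round(ratio * length(idx))
      train <- c(train, idx[seq_len(nTr)])
      blind <- c(blind, idx[-seq_len(nTr)])
    }
  })
  if (!length(train) || !length(blind) ||
      length(unique(labels[train])) < 2 || length(unique(labels[blind])) < 2)
    stop("stratification error: a class vanished from one side of the split")
  train <- sort(train); blind <- sort(blind)
  if (is(x, "PeakTable"))
    list(train = x[, train], blind = x[, blind],
         trainIdx = train, blindIdx = blind)
  else list(trainIdx = train, blindIdx = blind)
}

#' Classify blind samples with a sub-model ensemble
#'
#' Each sub-model standardizes the blind features with its own
#' train-partition statistics and votes by thresholding its output at 0.5;
#' the ensemble output is the fraction of votes for the positive class
#' (the second class name), the predicted class the majority vote (tie:
#' positive class) and the 95% CI half-width `2 * sqrt(p(1-p)/(n-1))`
#' with p the vote fraction and n the ensemble size.
#'
#' @param ensemble an `AnnEnsemble` from [fitFinalEnsemble()].
#' @param blind the blind [PeakTable-class] (same peak set as the
#'   training table the ensemble was fitted on).
#' @return an `EnsemblePrediction` `data.frame`: `sampleId`, vote counts
#'   for both classes, `output`, `ciHalfwidth`, `predicted`, `target`,
#'   `correct`; the n_models x n_samples 0/1 vote matrix is attached as
#'   attribute `"votes"`.
#' @export
ensemblePredict <- function(ensemble, blind) {
  stopIfNot(is(blind, "PeakTable"), "'blind' must be a PeakTable")
  if (!all(ensemble$featureIndices <= nrow(blind)) ||
      max(abs(mz(blind)[ensemble$featureIndices] - ensemble$featureMz)) > 1e-6)
    stop("blind table does not carry the ensemble's peak panel")
  X <- featureMatrix(blind)[, ensemble$featureIndices, drop = FALSE]
  nMod <- length(ensemble$models)
  votes <- vapply(ensemble$models, function(m) {
    Xs <- zscoreApply(X, list(center = m$center, scale = m$scale))
    as.integer(ann_predict_cpp(m$W1, m$W2, Xs) >= 0.5)
  }, integer(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))      # samples x models
  v1 <- rowSums(votes)
  p <- v1 / nMod
  cn <- ensemble$classNames
  predicted <- ifelse(v1 * 2 >= nMod, cn[2], cn[1])   # tie -> positive
  target <- classLabels(blind)
  out <- data.frame(
    sampleId = sampleIds(blind),
    votesClass0 = nMod - v1, votesClass1 = v1,
    output = p,
    ciHalfwidth = 2 * sqrt(p * (1 - p) / (nMod - 1)),
    predicted = predicted, target = target,
    correct = !is.na(target) & predicted == target)
  names(out)[2:3] <- paste0("votes_", cn)
  attr(out, "votes") <- t(votes)              # models x samples
  attr(out, "classNames") <- cn
  class(out) <- c("EnsemblePrediction", "data.frame")
  out
}

#' Per-class true- and false-positive rates
#'
#' For each class c: TPR = 100 TP/(TP+FN) with c as the positive class,
#' FPR = 100 FP/(FP+TN).  Pass pooled per-sub-model decisions to obtain
#' sub-model-level rates.
#'
#' @param predicted predicted class labels.
#' @param labels true class labels (same length).
#' @return `data.frame` with one row per class: `class`, `tpr`, `fpr`
#'   (percent) and the `tp`/`fp`/`tn`/`fn` counts.
#' @export
confusionRates <- function(predicted, labels) {
  stopIfNot(length(predicted) == length(labels),
            "predictions and labels must be aligned")
  cls <- unique(labels)
  if (length(cls) < 2)
    stop("undefined rate: empty class (only '", cls, "' present)")
  do.call(rbind, lapply(cls, function(c) {
    tp <- sum(predicted == c & labels == c)
    fn <- sum(predicted != c & labels == c)
    fp <- sum(predicted == c & labels != c)
    tn <- sum(predicted != c & labels != c)
    data.frame(class = c, tpr = 100 * tp / (tp + fn),
               fpr = 100 * fp / (fp + tn),
               tp = tp, fp = fp, tn = tn, fn = fn)
  }))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct ensemble outputs plus
#' sentinels; samples tied at one output value move simultaneously, so the
#' curve is well defined under ties.  The AUC is the trapezoidal area and
#' equals the tie-corrected Mann-Whitney statistic.
#'
#' @param outputs per-sample scores in [0, 1] (vote fractions for the
#'   positive class).
#' @param labels true class labels.
#' @param positive the positive class; default the second of the two
#'   label values in first-appearance order.
#' @return a `RocCurve` list: `points` (`data.frame` of `fpr`, `tpr`,
#'   `threshold`, ascending) and `auc`.
#' @export
rocAuc <- function(outputs, labels, positive = NULL) {
  stopIfNot(length(outputs) == length(labels),
            "outputs and labels must be aligned")
  cn <- unique(labels)
  if (length(cn) < 2)
    stop("undefined AUC: need both classes among the labels")
  if (is.null(positive)) positive <- cn[2]
  isPos <- labels == positive
  nPos <- sum(isPos); nNeg <- sum(!isPos)
  thr <- c(Inf, sort(unique(outputs), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(outputs >= t & isPos) / nPos, 0)
  fpr <- vapply(thr, function(t) sum(outputs >= t & !isPos) / nNeg, 0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
                 auc = auc, positive = positive),
            class = c("RocCurve", "list"))
}
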