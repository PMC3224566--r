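# Independent oracles and small fixture builders used across the suite.

# --- run-level, regex-based re-implementation of the peak-region scanner --
# Works on maximal 0- and 1-runs extracted with gregexpr and closes regions
# by arithmetic on run coordinates; deliberately a different construction
# from the package's element-walking scanner.

.runsOf <- function(s, pat) {
  m <- gregexpr(pat, s)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), len = integer()))
  data.frame(start = as.integer(m), len = attr(m, "match.length"))
}

bruteRegions <- function(signs, axis, meanInt, params) {
  s <- paste(signs, collapse = "")
  zr <- .runsOf(s, "0+")
  or <- .runsOf(s, "1+")
  L <- length(signs)
  npts <- L + 1
  thr <- function(m) params$minOneRun[max(sum(m >= params$checkpoints), 1)]
  out <- list()
  cursor <- 1
  lastEnd <- 0
  repeat {
    opened <- FALSE
    for (z in seq_len(nrow(zr))) {
      zs <- zr$start[z]; ze <- zs + zr$len[z] - 1
      if (ze < cursor) next
      eff <- max(zs, cursor)
      if (ze - eff + 1 >= params$minZeroRun) {
        opened <- TRUE
        break
      }
    }
    if (!opened) break
    P0 <- max(eff, lastEnd + 1)
    cap <- min(P0 + params$maxRegionPoints - 1, npts)
    k <- thr(axis[P0])
    closePoint <- Inf
    for (o in seq_len(nrow(or))) {
      os <- or$start[o]
      if (os > ze && or$len[o] >= k) { closePoint <- os + or$len[o]; break }
    }
    if (closePoint <= cap) {
      Pend <- closePoint; cursor <- Pend
    } else if (cap < npts) {
      Pend <- cap; cursor <- cap
    } else {
      Pend <- npts; cursor <- L + 1
    }
    out[[length(out) + 1]] <- c(P0, Pend)
    lastEnd <- Pend
    if (cursor > L) break
  }
  if (!length(out))
    return(data.frame(startIdx = integer(), endIdx = integer(),
                      magnitude = numeric()))
  df <- do.call(rbind, out)
  res <- data.frame(startIdx = df[, 1], endIdx = df[, 2])
  res$magnitude <- mapply(function(a, b)
    max(meanInt[a:b]) - min(meanInt[a], meanInt[b]),
    res$startIdx, res$endIdx)
  res[res$magnitude >= params$minMagnitude, , drop = FALSE]
}

# --- tie-corrected Mann-Whitney AUC --------------------------------------
mwAuc <- function(outputs, labels, positive) {
  isPos <- labels == positive
  r <- rank(outputs)
  n1 <- sum(isPos); n0 <- sum(!isPos)
  (sum(r[isPos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- small fixture builders ----------------------------------------------

# Direct peak table: p features over two classes; `informative` columns get
# a mean shift of `effect` in the second class.  No preprocessing involved.
makeToyTable <- function(nPerClass = c(20, 20), p = 10, informative = 1,
                         effect = 3, seed = 1, classNames = c("a", "b")) {
  withr::with_seed(seed, {
    n <- sum(nPerClass)
    X <- matrix(rnorm(n * p), n, p)
    lab <- rep(classNames, nPerClass)
    for (j in seq_len(informative))
      X[lab == classNames[2], j] <- X[lab == classNames[2], j] + effect
    ids <- sprintf("s%03d", seq_len(n))
    PeakTable(labelMz = 1000 + 10 * seq_len(p), intensity = t(X),
              sampleIds = ids, labels = lab)
  })
}

# A deterministic "constant-output" ANN ensemble: each sub-model votes a
# fixed class via its output bias, letting vote arithmetic be tested
# without training.
makeVotingEnsemble <- function(votesFor1, nModels, nFeatures = 2,
                               classNames = c("c0", "c1")) {
  models <- lapply(seq_len(nModels), function(k) {
    b <- if (k <= votesFor1) 5 else -5         # (tanh(+-5)+1)/2 ~ 1 or 0
    list(W1 = matrix(0, nFeatures + 1, 2), W2 = c(0, 0, b),
         center = rep(0, nFeatures), scale = rep(1, nFeatures))
  })
  structure(list(models = models, featureIndices = seq_len(nFeatures),
                 featureMz = 1000 + 10 * seq_len(nFeatures),
                 classNames = classNames,
                 params = stepwiseParams()),
            class = c("AnnEnsemble", "list"))
}

# Blind table matching makeVotingEnsemble's feature panel.
makeBlindTable <- function(n = 1, classNames = c("c0", "c1"),
                           labels = rep(classNames[1], n), nFeatures = 2) {
  PeakTable(labelMz = 1000 + 10 * seq_len(nFeatures),
            intensity = matrix(rnorm(nFeatures * n), nFeatures, n),
            sampleIds = sprintf("blind%02d", seq_len(n)), labels = labels)
}
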