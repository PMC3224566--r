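# Monte-Carlo splits, backprop training and forward stepwise ranking.

test_that("MCCV 60:20:20 splits give 41/14/14 from 69 and 67/22/22 from 111", {
  m69 <- mccvSplit(rep(c("a", "b"), c(34, 35)), seed = 1)
  expect_equal(lengths(m69), c(train = 41L, test = 14L, valid = 14L))
  m111 <- mccvSplit(rep(c("a", "b"), c(49, 62)), seed = 1)
  expect_equal(lengths(m111), c(train = 67L, test = 22L, valid = 22L))
})

test_that("MCCV partitions are disjoint, exhaustive and stratified", {
  withr::with_seed(10, {
    for (k in 1:100) {
      n <- sample(8:500, 1)
      nA <- sample(3:(n - 3), 1)
      labels <- sample(rep(c("a", "b"), c(nA, n - nA)))
      sp <- try(mccvSplit(labels, seed = k), silent = TRUE)
      if (inherits(sp, "try-error")) {
        # only acceptable failure: a class too small for three partitions
        expect_lt(min(nA, n - nA), 5)
        next
      }
      all3 <- c(sp$train, sp$test, sp$valid)
      expect_equal(sort(all3), seq_len(n))
      expect_equal(anyDuplicated(all3), 0L)
      for (part in sp)
        expect_equal(length(unique(labels[part])), 2)
    }
  })
})

test_that("training is deterministic and fits a constant target via bias", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40), 20, 2)
    y <- rep(0, 20)
    p <- stepwiseParams(maxEpochs = 500, windowEpochs = 200)
    m1 <- trainAnn(X, y, X, y, p, seed = 42)
    m2 <- trainAnn(X, y, X, y, p, seed = 42)
    expect_identical(m1$W1, m2$W1)
    expect_identical(m1$W2, m2$W2)
    expect_lt(m1$trainMse, 0.01)
    expect_lte(m1$epochs, 500)
    # predictions live in [0, 1]
    out <- predictAnn(m1, X)
    expect_true(all(out >= 0 & out <= 1))
  })
})

test_that("feature-set scoring separates signal from null features", {
  # two far clusters on one feature: near-zero test error
  sepTab <- makeToyTable(nPerClass = c(20, 20), p = 2, informative = 1,
                         effect = 8, seed = 8)
  p <- stepwiseParams(nResamples = 10, seed = 2)
  errSep <- scoreFeatureSet(sepTab, 1, p)
  expect_lt(errSep[["test"]], 0.05)

  # a pure-noise feature on balanced classes: MSE of a ~0.5 predictor
  nullTab <- makeToyTable(nPerClass = c(20, 20), p = 2, informative = 0,
                          seed = 9)
  errNull <- scoreFeatureSet(nullTab, 1, p)
  expect_lt(abs(errNull[["test"]] - 0.25), 0.05)

  # single resample, fixed seed: a deterministic triple
  p1 <- stepwiseParams(nResamples = 1, seed = 5)
  expect_identical(scoreFeatureSet(sepTab, 1, p1),
                   scoreFeatureSet(sepTab, 1, p1))
})

test_that("stepwise ranking finds a single planted marker at rank 1", {
  hits <- 0
  p <- stepwiseParams(nResamples = 10, maxSteps = 1, seed = 0)
  for (s in 1:10) {
    tab <- makeToyTable(nPerClass = c(25, 25), p = 30, informative = 1,
                        effect = 3, seed = 200 + s)
    panel <- stepwiseRank(tab, p)
    if (attr(panel, "featureIndices")[1] == 1L) hits <- hits + 1
  }
  expect_gte(hits, 9)   # >= 90% of replications
})

test_that("panel length, ion distinctness and column-order invariance hold", {
  tab <- makeToyTable(nPerClass = c(15, 15), p = 8, informative = 2,
                      effect = 3, seed = 12)
  p <- stepwiseParams(nResamples = 5, maxSteps = 4, seed = 3)
  panel <- stepwiseRank(tab, p)
  expect_equal(nrow(panel), 4)
  expect_equal(panel$rank, 1:4)
  expect_equal(anyDuplicated(panel$ion), 0L)
  expect_true(all(panel[c("avgTrainError", "avgTestError",
                          "avgValidError")] >= 0))

  # repeated ranking under the same seed is identical, and relabelling the
  # peaks (same data, shifted m/z labels) selects the same columns: the
  # choice depends only on the data and the shared resample schedule
  expect_identical(stepwiseRank(tab, p), panel)
  tabShift <- PeakTable(labelMz = mz(tab) + 0.5,
                        intensity = t(featureMatrix(tab)),
                        sampleIds = sampleIds(tab),
                        labels = classLabels(tab))
  panelShift <- stepwiseRank(tabShift, p)
  expect_identical(attr(panelShift, "featureIndices"),
                   attr(panel, "featureIndices"))

  # fewer peaks than steps: truncated panel with a warning
  small <- makeToyTable(nPerClass = c(15, 15), p = 3, informative = 1,
                        seed = 13)
  expect_warning(panelS <- stepwiseRank(small,
                                        stepwiseParams(nResamples = 3,
                                                       maxSteps = 10,
                                                       seed = 1)),
                 "truncated")
  expect_equal(nrow(panelS), 3)
})

test_that("adding a second independent marker lowers the test error", {
  lower <- 0
  for (s in 1:5) {
    tab <- makeToyTable(nPerClass = c(20, 20), p = 10, informative = 2,
                        effect = 2, seed = 300 + s)
    p <- stepwiseParams(nResamples = 8, maxSteps = 2, seed = s)
    panel <- stepwiseRank(tab, p)
    if (panel$avgTestError[2] <= panel$avgTestError[1]) lower <- lower + 1
  }
  expect_gte(lower, 3)   # majority of seeds
})

test_that("the final ensemble keeps one sub-model per resample on the panel", {
  tab <- makeToyTable(nPerClass = c(15, 15), p = 6, informative = 2,
                      effect = 4, seed = 14)
  p <- stepwiseParams(nResamples = 7, maxSteps = 2, seed = 4)
  panel <- stepwiseRank(tab, p)
  ens1 <- fitFinalEnsemble(tab, panel, p)
  ens2 <- fitFinalEnsemble(tab, panel, p)
  expect_length(ens1$models, 7)
  expect_identical(lapply(ens1$models, `[[`, "W1"),
                   lapply(ens2$models, `[[`, "W1"))
  expect_equal(ens1$featureMz, panel$ion)
  for (m in ens1$models) expect_length(m$center, nrow(panel))
})
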