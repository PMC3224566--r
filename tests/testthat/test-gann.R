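# GA + feedforward-network feature reduction.

test_that("feature genes decode by floor with clamping", {
  expect_equal(decodeFeatures(0, 2560), 1L)
  expect_equal(decodeFeatures(0.999999, 2560), 2560L)
  expect_equal(decodeFeatures(0.5, 2560), 1281L)    # floor(1280) 0-based
  expect_equal(decodeFeatures(c(0.1, 0.1), 10), c(2L, 2L))  # duplicates ok
})

test_that("the reference forward pass matches closed-form tanh composition", {
  # all-zero weights give zero outputs
  expect_equal(annForward(rep(0, 48), rnorm(20)), c(0, 0))
  # outputs bounded in (-1, 1)
  withr::with_seed(1, {
    for (k in 1:10) {
      o <- annForward(runif(48, -1, 1), rnorm(20) * 10)
      expect_true(all(abs(o) < 1))
    }
  })
  # hand-set 1-feature net: 1-2-2 has (1+1)*2 + (2+1)*2 = 10 weights
  w <- c(0.3, -0.2,   # hidden 1: w, bias
         0.5, 0.1,    # hidden 2: w, bias
         1, -1, 0.2,  # out 1: h1, h2, bias
         -0.5, 0.25, 0)
  x <- 0.7
  h <- tanh(c(0.3 * x - 0.2, 0.5 * x + 0.1))
  o <- tanh(c(sum(c(1, -1) * h) + 0.2, sum(c(-0.5, 0.25) * h)))
  expect_equal(annForward(w, x, hiddenUnits = 2, outputUnits = 2), o,
               tolerance = 1e-12)
})

test_that("fitness counts argmax matches with ties going to class 0", {
  withr::with_seed(2, {
    X <- matrix(rnorm(30 * 6), 30, 6)
    y <- rep(c(0L, 1L), 15)
    # all-zero weights tie every sample -> predicted class 0 everywhere
    chromW <- rep(0, (6 + 1) * 2 + 3 * 2)
    f <- gannFitness(rep(0.1, 6), chromW, X, y, 2, 2)
    expect_equal(f, sum(y == 0L))
    # fitness is bounded by the sample count
    f2 <- gannFitness(runif(6), runif(20, -1, 1), X, y, 2, 2)
    expect_gte(f2, 0); expect_lte(f2, 30)
  })
})

test_that("runs are deterministic and the compiled fitness matches the R recount", {
  tab <- makeToyTable(nPerClass = c(15, 15), p = 12, informative = 2,
                      effect = 3, seed = 4)
  gp <- gannParams(populationSize = 50, chromFeatures = 6,
                   evaluationBudget = 2000)
  r1 <- runGann(tab, gp, seed = 9)
  r2 <- runGann(tab, gp, seed = 9)
  expect_identical(r1$bestChromosome, r2$bestChromosome)
  expect_identical(r1$trajectory, r2$trajectory)

  # independent R-level recount of the best chromosome's fitness
  X <- featureMatrix(tab)
  Xs <- maldiPanel:::zscoreApply(X, maldiPanel:::zscoreStats(X))
  y01 <- as.integer(classLabels(tab) == "b")
  recount <- gannFitness(r1$bestChromosome$featureGenes,
                         r1$bestChromosome$weightGenes, Xs, y01,
                         gp$hiddenUnits, gp$outputUnits)
  expect_equal(r1$bestFitness, recount)
})

test_that("elitism keeps the best-fitness trajectory non-decreasing", {
  tab <- makeToyTable(nPerClass = c(10, 10), p = 8, informative = 1,
                      seed = 5)
  for (s in 1:5) {
    r <- runGann(tab, gannParams(populationSize = 30, chromFeatures = 4,
                                 evaluationBudget = 1500), seed = s)
    expect_false(is.unsorted(r$trajectory))
    expect_equal(max(r$trajectory), r$bestFitness)
  }
})

test_that("a linearly separable toy is solved within the evaluation budget", {
  # 40 samples, 2 informative + 10 noise features, wide margin: a
  # separating 20-2-2 weight vector exists (verified by construction via
  # a logistic fit in the oracle below), so the GA should find a perfect
  # classifier almost always
  hits <- 0
  for (s in 1:20) {
    tab <- makeToyTable(nPerClass = c(20, 20), p = 12, informative = 2,
                        effect = 4, seed = 100 + s)
    # oracle: the classes are separable by a linear rule on feature 1
    X <- featureMatrix(tab)
    y01 <- as.integer(classLabels(tab) == "b")
    cut <- mean(range(X[, 1]))
    sep <- max(mean((X[, 1] > cut) == y01), mean((X[, 1] <= cut) == y01))
    expect_gt(sep, 0.9)
    r <- runGann(tab, gannParams(populationSize = 100, chromFeatures = 6,
                                 evaluationBudget = 20000), seed = s)
    if (r$bestFitness == 40) hits <- hits + 1
  }
  expect_gte(hits, 19)   # >= 95% of seeds
})

test_that("aggregation ranks features by selection frequency", {
  tab <- makeToyTable(nPerClass = c(10, 10), p = 10, informative = 1,
                      seed = 6)
  r <- runGann(tab, gannParams(populationSize = 30, chromFeatures = 5,
                               evaluationBudget = 1000), seed = 1)
  rk1 <- aggregateRuns(list(r), topM = 5)
  expect_true(all(rk1$ranking$frequency %in% c(0L, 1L)))
  expect_setequal(intersect(rk1$topFeatures, r$bestFeatures), r$bestFeatures)

  # a feature present in every run's best subset ranks first
  fake <- lapply(1:50, function(k) {
    counts <- integer(10); counts[3] <- 2L
    counts[sample(setdiff(1:10, 3), 2)] <- 1L
    list(selectionCounts = counts, featureNames = NULL)
  })
  rk <- aggregateRuns(fake, topM = 3)
  expect_equal(rk$ranking$feature[1], 3)
  expect_equal(rk$ranking$frequency[1], 50L)
  # ties break by ascending feature index
  tied <- list(list(selectionCounts = c(0L, 1L, 1L, 0L), featureNames = NULL))
  expect_equal(aggregateRuns(tied, topM = 4)$ranking$feature, c(2, 3, 1, 4))
})

test_that("planted markers dominate selection frequencies on synthetic cohorts", {
  cfg <- simConfig(nPerClass = c(30, 30), mzRange = c(800, 1300),
                   gridStep = 0.1, nPeaks = 20, nInformative = 10,
                   foldChange = 3, noiseSd = 2, seed = 55)
  coh <- generateCohort(cfg)
  pp <- preprocessCohort(coh$spectra, gridStep = 0.1,
                         cropRange = c(800, 1300))
  tab <- pp$peakTable
  planted <- which(vapply(seq_len(nrow(tab)), function(r)
    any(peakInfo(tab)$startMz[r] <= coh$truth$informativeLocations &
          peakInfo(tab)$endMz[r] >= coh$truth$informativeLocations), TRUE))
  expect_length(planted, 10)

  gp <- gannParams(evaluationBudget = 10000, nRuns = 50, seed = 7)
  red <- reduceFeatures(tab, gp, topM = 100)
  freq <- integer(nrow(tab))
  freq[red$ranking$ranking$feature] <- red$ranking$ranking$frequency
  ratio <- mean(freq[planted]) / max(mean(freq[-planted]), 1e-9)
  expect_gte(ratio, 5)
  # all planted peaks inside the top-100 focused subset
  expect_true(all(planted %in% red$ranking$topFeatures))
})
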