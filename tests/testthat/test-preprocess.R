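# Grid merge, cropping, sign encoding, region detection and binning.

test_that("merging preserves identical-axis cohorts and interpolates gaps", {
  ax <- seq(800, 810, by = 0.5)
  s1 <- MassSpectrum(ax, seq_along(ax), "s1", "A")
  s2 <- MassSpectrum(ax, rev(seq_along(ax)), "s2", "B")
  g <- mergeToGrid(list(s1, s2), gridStep = 0.5, smoothWindow = 0)
  expect_equal(mz(g), ax)
  expect_equal(unname(featureMatrix(g)["s1", ]), as.numeric(seq_along(ax)))
  expect_equal(unname(featureMatrix(g)["s2", ]),
               as.numeric(rev(seq_along(ax))))

  # linear interpolation fills a missing point exactly
  s3 <- MassSpectrum(c(999.98, 1000.02), c(8, 12), "s3")
  s4 <- MassSpectrum(c(999.98, 1000.00, 1000.02), c(8, 10, 12), "s4")
  g2 <- mergeToGrid(list(s3, s4), gridStep = 0.02, smoothWindow = 0)
  at1000 <- which.min(abs(mz(g2) - 1000))
  expect_equal(unname(assay(g2)[at1000, "s3"]), 10, tolerance = 1e-9)

  # smoothing preserves constant spectra
  s5 <- MassSpectrum(seq(800, 805, 0.1), rep(7, 51), "s5")
  s6 <- MassSpectrum(seq(800, 805, 0.1), rep(7, 51), "s6")
  g3 <- mergeToGrid(list(s5, s6), gridStep = 0.1, smoothWindow = 0.4)
  expect_true(all(abs(assay(g3) - 7) < 1e-12))

  # out-of-support grid points are zero-filled, not extrapolated
  s7 <- MassSpectrum(c(800, 801), c(5, 5), "s7")
  s8 <- MassSpectrum(c(803, 804), c(9, 9), "s8")
  g4 <- mergeToGrid(list(s7, s8), gridStep = 0.5, smoothWindow = 0)
  expect_equal(unname(assay(g4)[mz(g4) > 801, "s7"]),
               rep(0, sum(mz(g4) > 801)))

  expect_error(mergeToGrid(list(s7, s8), 0.5, 0, range = c(900, 950)),
               "s7")
})

test_that("cropping restricts the axis and validates the window", {
  ax <- seq(700, 4000, by = 1)
  g <- SpectrumGrid(ax, matrix(1, length(ax), 2), c("a", "b"), c("A", "B"))
  cr <- cropGrid(g, 800, 3500)
  expect_gte(min(mz(cr)), 800)
  expect_lte(max(mz(cr)), 3500)
  full <- cropGrid(g, 700, 4000)
  expect_equal(dim(full), dim(g))
  expect_error(cropGrid(g, 5000, 6000), "does not intersect")
})

test_that("the mean spectrum is the per-point arithmetic mean", {
  g <- SpectrumGrid(c(1, 2), matrix(c(1, 3, 3, 5), 2), c("a", "b"),
                    c("A", "B"))
  expect_equal(intensity(meanSpectrum(g)), c(2, 4))
  g1 <- SpectrumGrid(c(1, 2), matrix(c(4, 9), 2), "a", "A")
  expect_equal(intensity(meanSpectrum(g1)), c(4, 9))
  # 100 all-zero samples plus one all-tens
  g2 <- SpectrumGrid(c(1, 2), cbind(matrix(0, 2, 100), c(10, 10)),
                     sprintf("s%d", 1:101), rep(c("A", "B"), c(50, 51)))
  expect_equal(intensity(meanSpectrum(g2)), rep(10 / 101, 2))
})

test_that("sign encoding marks increases 0 and ties/decreases 1", {
  ms <- function(y) new("MeanSpectrum", mz = seq_along(y), intensity = y)
  expect_equal(encodeSigns(ms(c(1, 2, 3, 2, 1))), c(0L, 0L, 1L, 1L))
  expect_equal(encodeSigns(ms(c(5, 5))), 1L)
  expect_equal(encodeSigns(ms(1:10)), rep(0L, 9))
  expect_equal(encodeSigns(ms(10:1)), rep(1L, 9))
})

test_that("region detection follows the run contract on worked examples", {
  bp <- boundaryParams(minZeroRun = 3, minOneRun = rep(3, 5))
  ms <- function(y, mzv = 800 + seq_along(y))
    new("MeanSpectrum", mz = mzv, intensity = y)

  # ascent of 4, descent of 3 over 8 points: one region spanning all 8
  m <- ms(c(1, 2, 3, 4, 5, 4, 3, 2))
  r <- detectPeakRegions(encodeSigns(m), m, bp)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$startIdx, r$endIdx), c(1L, 8L))
  expect_equal(r$labelMz, median(mz(m)))
  expect_equal(r$magnitude, 5 - min(1, 2))

  # all-decreasing: no region
  m2 <- ms(10:1)
  expect_equal(nrow(detectPeakRegions(encodeSigns(m2), m2, bp)), 0)

  # a 2-long ascent cannot open a region when 3 are required
  m3 <- ms(c(1, 2, 3, 2, 1, 0.5, 0.2, 0.1))
  expect_equal(nrow(detectPeakRegions(encodeSigns(m3), m3, bp)), 0)

  # magnitude filter discards shallow regions
  m4 <- ms(c(1, 1.01, 1.02, 1.03, 1.0, 0.9, 0.8))
  bpMag <- boundaryParams(minOneRun = rep(3, 5), minMagnitude = 0.5)
  expect_equal(nrow(detectPeakRegions(encodeSigns(m4), m4, bpMag)), 0)
  bp0 <- boundaryParams(minOneRun = rep(3, 5))
  expect_equal(nrow(detectPeakRegions(encodeSigns(m4), m4, bp0)), 1)

  # checkpoint segments pick their own descent thresholds: the same shape
  # closes after a 4-descent in the first segment (k = 3) but stays open
  # beyond m/z 3000 (k = 5) and absorbs the following ascent
  y <- c(1, 2, 3, 4, 5, 4, 3, 2, 1, 2, 3, 4)
  mHi <- ms(y, mzv = 3000 + seq_along(y))
  rHi <- detectPeakRegions(encodeSigns(mHi), mHi, boundaryParams())
  expect_equal(nrow(rHi), 1)
  expect_equal(rHi$endIdx, length(y))   # closed by the sequence end
  mLo <- ms(y, mzv = 800 + seq_along(y))
  rLo <- detectPeakRegions(encodeSigns(mLo), mLo, boundaryParams())
  expect_equal(nrow(rLo), 2)
  expect_equal(rLo$endIdx[1], 9L)       # full descent included
})

test_that("regions are truncated at the point cap and scanning resumes", {
  y <- c(1:6, rep(c(6, 5.9), 20), 5, 4, 3, 2, 1)
  m <- new("MeanSpectrum", mz = 800 + seq_along(y), intensity = y)
  bp <- boundaryParams(minOneRun = rep(3, 5), maxRegionPoints = 10)
  r <- detectPeakRegions(encodeSigns(m), m, bp)
  expect_true(all(r$nPoints <= 10))
  expect_equal(r$startIdx[1], 1L)
  expect_equal(r$endIdx[1], 10L)
  # disjoint and ascending
  expect_true(all(r$startIdx[-1] > r$endIdx[-nrow(r)]))
})

test_that("binning labels by median m/z and averages region intensities", {
  ax <- c(1000.00, 1000.02, 1000.04, 1000.06)
  g <- SpectrumGrid(ax, matrix(c(2, 4, 6, 0, 1, 1, 1, 9), 4),
                    c("s1", "s2"), c("A", "B"))
  reg <- data.frame(startIdx = 1L, endIdx = 3L, startMz = ax[1],
                    endMz = ax[3], labelMz = ax[2], nPoints = 3L,
                    magnitude = 1)
  pt <- binRegions(g, reg)
  expect_equal(mz(pt), 1000.02)
  expect_equal(unname(featureMatrix(pt)[, 1]), c(4, 1))

  # even-length region: label is the mean of the two central m/z values
  reg4 <- data.frame(startIdx = 1L, endIdx = 4L, startMz = ax[1],
                     endMz = ax[4], labelMz = median(ax), nPoints = 4L,
                     magnitude = 1)
  pt4 <- binRegions(g, reg4)
  expect_equal(mz(pt4), (ax[2] + ax[3]) / 2)
  expect_equal(unname(featureMatrix(pt4)["s2", ]), mean(c(1, 1, 1, 9)))
  ptMax <- binRegions(g, reg4, aggregate = "max")
  expect_equal(unname(featureMatrix(ptMax)["s2", ]), 9)

  # overlapping regions are rejected
  regBad <- rbind(reg, data.frame(startIdx = 2L, endIdx = 4L, startMz = ax[2],
                                  endMz = ax[4], labelMz = ax[3],
                                  nPoints = 3L, magnitude = 1))
  expect_error(binRegions(g, regBad), "disjoint")

  # cell values stay within the sample's range over the region
  withr::with_seed(7, {
    gg <- SpectrumGrid(seq(800, 809, 1), matrix(runif(30), 10),
                       c("x", "y", "z"), c("A", "A", "B"))
    rr <- data.frame(startIdx = c(1L, 6L), endIdx = c(4L, 9L),
                     startMz = c(800, 805), endMz = c(803, 808),
                     labelMz = c(801.5, 806.5), nPoints = c(4L, 4L),
                     magnitude = c(1, 1))
    ptp <- binRegions(gg, rr)
    for (s in 1:3) for (r in 1:2) {
      vals <- assay(gg)[rr$startIdx[r]:rr$endIdx[r], s]
      expect_gte(featureMatrix(ptp)[s, r], min(vals))
      expect_lte(featureMatrix(ptp)[s, r], max(vals))
    }
  })
})

test_that("the preprocessing pipeline is sample-permutation invariant", {
  cfg <- simConfig(nPerClass = c(4, 4), mzRange = c(800, 900),
                   gridStep = 0.05, nPeaks = 6, nInformative = 2,
                   noiseSd = 0.5, seed = 17)
  coh <- generateCohort(cfg)
  p1 <- preprocessCohort(coh$spectra, gridStep = 0.05)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  p2 <- preprocessCohort(coh$spectra[perm], gridStep = 0.05)
  expect_equal(mz(p2$peakTable), mz(p1$peakTable))
  expect_equal(featureMatrix(p2$peakTable),
               featureMatrix(p1$peakTable)[perm, ])
})

test_that("noise-free planted peaks are each detected as one region", {
  cfg <- simConfig(nPerClass = c(3, 3), mzRange = c(800, 1500),
                   gridStep = 0.05, nPeaks = 12, nInformative = 3,
                   noiseSd = 0, driftSd = 0, intensityCv = 0, seed = 23)
  coh <- generateCohort(cfg)
  pp <- preprocessCohort(coh$spectra, gridStep = 0.05,
                         cropRange = c(800, 1500))
  expect_equal(nrow(pp$regions), 12)
  hits <- vapply(coh$templates$location, function(l)
    sum(pp$regions$startMz <= l & pp$regions$endMz >= l), 0L)
  expect_true(all(hits == 1L))
})
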