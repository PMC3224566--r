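# Mean-spectrum sign-encoding preprocessing: merge spectra onto a uniform
# m/z grid with 0.2 Da pre-smoothing, crop to the analysis range, encode
# the cohort mean spectrum as increase/decrease signs, delimit peak regions
# by runs of ascent and descent signs, and bin regions into a samples x
# peaks table labelled by median m/z.

#' Peak-region boundary parameters
#'
#' The lower boundary of a peak region is the start of a run of at least
#' `minZeroRun` consecutive increase signs; the upper boundary is the end
#' of the first subsequent run of at least k consecutive decrease signs,
#' where k depends on which checkpoint segment the region starts in
#' (segments are half-open, lower-inclusive; thresholds rise with m/z
#' because peaks broaden at high mass).  A region is truncated at
#' `maxRegionPoints` grid points, and regions whose mean-spectrum magnitude
#' (region maximum minus edge minimum) falls below `minMagnitude` are
#' discarded.
#'
#' @param minZeroRun minimum ascent run opening a region (default 3).
#' @param checkpoints ascending m/z segment boundaries (Da).
#' @param minOneRun per-segment minimum descent run lengths, same length as
#'   `checkpoints`.
#' @param maxRegionPoints cap on grid points per region.
#' @param minMagnitude minimum mean-spectrum magnitude (0 = keep all).
#' @return a `BoundaryParams` (validated list).
#' @export
boundaryParams <- function(minZeroRun = 3,
                           checkpoints = c(800, 1400, 1900, 2400, 3000),
                           minOneRun = c(3, 3, 4, 4, 5),
                           maxRegionPoints = 200, minMagnitude = 0) {
  p <- list(minZeroRun = as.integer(minZeroRun),
            checkpoints = as.numeric(checkpoints),
            minOneRun = as.integer(minOneRun),
            maxRegionPoints = as.integer(maxRegionPoints),
            minMagnitude = minMagnitude)
  stopIfNot(p$minZeroRun >= 1, "minZeroRun must be >= 1")
  stopIfNot(length(p$minOneRun) == length(p$checkpoints),
            "minOneRun must have one entry per checkpoint")
  stopIfNot(!is.unsorted(p$checkpoints, strictly = TRUE),
            "checkpoints must be ascending")
  stopIfNot(p$maxRegionPoints > p$minZeroRun,
            "maxRegionPoints must exceed minZeroRun")
  class(p) <- c("BoundaryParams", "list")
  p
}

#' Merge raw spectra onto a shared uniform m/z grid
#'
#' Each spectrum is smoothed with a centered moving average of width
#' `smoothWindow` (in Da, over its native axis) and then linearly
#' interpolated onto a uniform grid of step `gridStep`.  Grid points
#' outside a sample's native range are filled with 0 (no signal is ever
#' extrapolated).
#'
#' @param spectra list of [MassSpectrum-class] objects (>= 2).
#' @param gridStep target grid step in Da (default 0.02).
#' @param smoothWindow moving-average window in Da (default 0.2; 0
#'   disables smoothing).
#' @param range optional (lo, hi) target range; the default spans the
#'   union of the native ranges.  A spectrum with no overlap with the
#'   target range raises an error naming the sample.
#' @return a [SpectrumGrid-class].
#' @export
mergeToGrid <- function(spectra, gridStep = 0.02, smoothWindow = 0.2,
                        range = NULL) {
  stopIfNot(length(spectra) >= 2, "need at least 2 spectra to merge")
  stopIfNot(gridStep > 0, "gridStep must be positive")
  los <- vapply(spectra, function(s) s@mz[1], 0)
  his <- vapply(spectra, function(s) s@mz[length(s@mz)], 0)
  if (is.null(range)) range <- c(min(los), max(his))
  for (k in seq_along(spectra))
    if (his[k] < range[1] || los[k] > range[2])
      stop("spectrum '", spectra[[k]]@sampleId,
           "' has no overlap with the target m/z range")
  axis <- gridStep * seq(ceiling(range[1] / gridStep - 1e-9),
                         floor(range[2] / gridStep + 1e-9))
  mat <- vapply(spectra, function(s) {
    y <- s@intensity
    if (smoothWindow > 0) {
      half <- smoothWindow / 2
      cs <- c(0, cumsum(y))
      i1 <- findInterval(s@mz - half - 1e-12, s@mz) + 1L
      i2 <- findInterval(s@mz + half + 1e-12, s@mz)
      y <- (cs[i2 + 1L] - cs[i1]) / (i2 - i1 + 1L)
    }
    out <- approx(s@mz, y, xout = axis, rule = 1)$y
    out[is.na(out)] <- 0
    out
  }, numeric(length(axis)))
  SpectrumGrid(axis, mat,
               sampleIds = vapply(spectra, function(s) s@sampleId, ""),
               labels = vapply(spectra, function(s) s@label, ""))
}

#' Crop a spectrum grid to an m/z window
#'
#' @param grid a [SpectrumGrid-class].
#' @param lo,hi inclusive m/z bounds (Da); the classical analysis window
#'   for tryptic peptide profiles is 800-3500.
#' @return the cropped [SpectrumGrid-class].
#' @export
cropGrid <- function(grid, lo = 800, hi = 3500) {
  stopIfNot(lo < hi, "crop bounds must satisfy lo < hi")
  keep <- which(mz(grid) >= lo & mz(grid) <= hi)
  if (!length(keep))
    stop("crop range [", lo, ", ", hi, "] does not intersect the grid axis")
  grid[keep, ]
}

#' Cohort mean spectrum
#'
#' Per-point arithmetic mean over all samples, regardless of class: region
#' boundaries are defined on the whole population so that the same bins
#' apply to every sample.
#'
#' @param grid a [SpectrumGrid-class] with at least one sample.
#' @return a [MeanSpectrum-class].
#' @export
meanSpectrum <- function(grid) {
  stopIfNot(ncol(grid) >= 1, "grid has no samples")
  new("MeanSpectrum", mz = mz(grid), intensity = rowMeans(assay(grid)))
}

#' Sign-encode a mean spectrum
#'
#' Compares each pair of adjacent m/z points: 0 marks an increase to the
#' next point, 1 a decrease or tie (a tie cannot start a peak ascent).
#'
#' @param mean a [MeanSpectrum-class] with at least 2 points.
#' @return integer vector over \{0, 1\} of length `length(mz(mean)) - 1`.
#' @examples
#' m <- new("MeanSpectrum", mz = 1:5, intensity = c(1, 2, 3, 2, 1))
#' encodeSigns(m)   # 0 0 1 1
#' @export
encodeSigns <- function(mean) {
  stopIfNot(length(mean@intensity) >= 2, "need at least 2 points to encode")
  as.integer(diff(mean@intensity) <= 0)
}

.oneRunThreshold <- function(startMz, params) {
  seg <- findInterval(startMz, params$checkpoints)
  params$minOneRun[max(seg, 1L)]   # below the first checkpoint: first segment
}

#' Delimit peak regions on a sign sequence
#'
#' Scans left to right: a region opens at the first index of a run of at
#' least `minZeroRun` consecutive 0s (ascent) and closes at the end of the
#' first subsequent run of at least k consecutive 1s (descent), k being the
#' checkpoint-segment threshold for the region's start m/z; the full
#' descent run is included in the region.  A region reaching
#' `maxRegionPoints` grid points is truncated there and scanning resumes; a
#' region still open at the end of the axis closes at the last point.
#' Regions below `minMagnitude` are discarded.  The output is a disjoint,
#' ascending set of regions.
#'
#' @param signs integer 0/1 vector from [encodeSigns()].
#' @param mean the [MeanSpectrum-class] the signs were computed from
#'   (`length(mz(mean)) == length(signs) + 1`).
#' @param params a [boundaryParams()].
#' @return `data.frame` with one row per region: `startIdx`, `endIdx`
#'   (inclusive grid indices), `startMz`, `endMz`, `labelMz` (median m/z of
#'   the region), `nPoints`, `magnitude` (mean-spectrum maximum minus edge
#'   minimum).  Zero rows when no region qualifies.
#' @export
detectPeakRegions <- function(signs, mean, params = boundaryParams()) {
  stopIfNot(length(signs) == length(mean@mz) - 1,
            "signs are inconsistent with the mean spectrum")
  axis <- mean@mz
  mi <- mean@intensity
  L <- length(signs)
  nPoints <- L + 1L
  starts <- integer(0); ends <- integer(0)
  lastEnd <- 0L
  i <- 1L
  while (i <= L) {
    if (signs[i] != 0L) { i <- i + 1L; next }
    j <- i
    while (j <= L && signs[j] == 0L) j <- j + 1L
    if (j - i < params$minZeroRun) { i <- j; next }
    P0 <- max(i, lastEnd + 1L)             # keep regions disjoint
    Pcap <- min(P0 + params$maxRegionPoints - 1L, nPoints)
    k <- .oneRunThreshold(axis[P0], params)
    pos <- j                               # first sign after the ascent run
    onerun <- 0L
    Pend <- NA_integer_
    while (pos <= L) {
      onerun <- if (signs[pos] == 1L) onerun + 1L else 0L
      endpt <- pos + 1L
      if (endpt > Pcap) { Pend <- Pcap; pos <- Pcap; break }
      if (onerun >= k && (pos == L || signs[pos + 1L] == 0L)) {
        Pend <- endpt; pos <- pos + 1L; break
      }
      pos <- pos + 1L
    }
    if (is.na(Pend)) {
      # sequence exhausted without a closing descent: close at the cap (and
      # resume scanning there) if the cap cuts the region, else at the end
      if (Pcap < nPoints) { Pend <- Pcap; pos <- Pcap }
      else { Pend <- nPoints; pos <- L + 1L }
    }
    starts <- c(starts, P0); ends <- c(ends, Pend)
    lastEnd <- Pend
    i <- pos
  }
  if (!length(starts))
    return(data.frame(startIdx = integer(), endIdx = integer(),
                      startMz = numeric(), endMz = numeric(),
                      labelMz = numeric(), nPoints = integer(),
                      magnitude = numeric()))
  magn <- mapply(function(a, b) max(mi[a:b]) - min(mi[a], mi[b]),
                 starts, ends)
  reg <- data.frame(
    startIdx = starts, endIdx = ends,
    startMz = axis[starts], endMz = axis[ends],
    labelMz = mapply(function(a, b) median(axis[a:b]), starts, ends),
    nPoints = ends - starts + 1L,
    magnitude = magn)
  reg[reg$magnitude >= params$minMagnitude, , drop = FALSE]
}

#' Bin peak regions into a samples-by-peaks table
#'
#' Each region becomes one feature labelled by the median m/z of its grid
#' points (even point count: mean of the two central values); the cell for
#' sample s and region r is the arithmetic mean of s's intensities over r.
#' The `"max"` aggregator (maximum intensity in the region) is supported
#' for comparison but tends to equalise the classes and is not the
#' default.
#'
#' @param grid a [SpectrumGrid-class].
#' @param regions region `data.frame` from [detectPeakRegions()].
#' @param aggregate `"mean"` (default) or `"max"`.
#' @return a [PeakTable-class].
#' @export
binRegions <- function(grid, regions, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopIfNot(nrow(regions) > 0, "no regions to bin")
  stopIfNot(max(regions$endIdx) <= nrow(grid) && min(regions$startIdx) >= 1,
            "regions fall outside the grid axis")
  ord <- order(regions$startIdx)
  regions <- regions[ord, , drop = FALSE]
  if (any(regions$startIdx[-1] <= regions$endIdx[-nrow(regions)]))
    stop("regions must be disjoint")
  A <- assay(grid)
  agg <- if (aggregate == "mean") colMeans else function(m) apply(m, 2, max)
  mat <- t(vapply(seq_len(nrow(regions)), function(r)
    agg(A[regions$startIdx[r]:regions$endIdx[r], , drop = FALSE]),
    numeric(ncol(grid))))
  PeakTable(labelMz = regions$labelMz, intensity = mat,
            sampleIds = sampleIds(grid), labels = classLabels(grid),
            regionInfo = regions[c("startMz", "endMz", "startIdx", "endIdx",
                                   "magnitude")])
}

#' Run the whole preprocessing chain on a cohort of spectra
#'
#' Merge, crop, mean spectrum, sign encoding, region detection and
#' binning in one call.
#'
#' @param spectra list of [MassSpectrum-class] objects.
#' @param gridStep,smoothWindow see [mergeToGrid()].
#' @param cropRange (lo, hi) analysis window in Da.
#' @param params a [boundaryParams()].
#' @param aggregate region aggregator, see [binRegions()].
#' @return list with `peakTable` ([PeakTable-class]), `regions`
#'   (`data.frame`), `mean` ([MeanSpectrum-class]) and `signs`.
#' @export
preprocessCohort <- function(spectra, gridStep = 0.02, smoothWindow = 0.2,
                             cropRange = c(800, 3500),
                             params = boundaryParams(),
                             aggregate = "mean") {
  grid <- mergeToGrid(spectra, gridStep, smoothWindow)
  grid <- cropGrid(grid, cropRange[1], cropRange[2])
  ms <- meanSpectrum(grid)
  signs <- encodeSigns(ms)
  regions <- detectPeakRegions(signs, ms, params)
  stopIfNot(nrow(regions) > 0, "no peak regions detected")
  list(peakTable = binRegions(grid, regions, aggregate),
       regions = regions, mean = ms, signs = signs)
}
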