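#' Mass-to-charge axis of a spectrum or grid
#'
#' @param x a [MassSpectrum-class], [SpectrumGrid-class],
#'   [MeanSpectrum-class] or [PeakTable-class] object.
#' @return numeric vector of m/z values in daltons (for `PeakTable`, the
#'   median m/z label of each peak region).
#' @export
setGeneric("mz", function(x) standardGeneric("mz"))

#' Intensity values
#'
#' @param x a [MassSpectrum-class] or [MeanSpectrum-class] object.
#' @return numeric vector of intensities (arbitrary units).
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' Sample identifiers
#'
#' @param x an object holding one or more samples.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Class labels
#'
#' @param x an object holding labelled samples.
#' @return character vector of class labels (may contain `NA` when
#'   unlabelled).
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Samples-by-features intensity matrix
#'
#' Returns the data in the orientation used by the modelling code: one row
#' per sample, one column per m/z point (for a [SpectrumGrid-class]) or per
#' peak region (for a [PeakTable-class]).
#'
#' @param x a `SpectrumGrid` or `PeakTable`.
#' @return numeric matrix, rows named by sample id.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Peak-region metadata of a peak table
#'
#' @param x a [PeakTable-class].
#' @return `data.frame` with one row per peak region: `labelMz` (median m/z
#'   of the region, the peak's name), `startMz`/`endMz` region bounds, and,
#'   when the table was produced by [binRegions()], the grid indices and
#'   mean-spectrum magnitude of the region.
#' @export
setGeneric("peakInfo", function(x) standardGeneric("peakInfo"))
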