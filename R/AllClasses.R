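#' One raw MALDI-TOF mass spectrum
#'
#' A single sample's (m/z, intensity) trace.  The m/z axis must be strictly
#' increasing, intensities non-negative and of the same length (at least 2
#' points).  An optional binary class label may be attached.
#'
#' @slot mz numeric, strictly increasing m/z values in daltons.
#' @slot intensity numeric, non-negative intensities, same length as `mz`.
#' @slot sampleId character scalar.
#' @slot label character scalar class tag, `NA` if unlabelled.
#'
#' @aliases MassSpectrum
#' @export
setClass("MassSpectrum",
  slots = c(mz = "numeric", intensity = "numeric",
            sampleId = "character", label = "character"))

setValidity("MassSpectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have the same length")
  if (length(object@mz) < 2)
    msg <- c(msg, "a spectrum needs at least 2 points")
  if (anyNA(object@mz) || anyNA(object@intensity))
    msg <- c(msg, "mz and intensity must not contain NA")
  else {
    if (any(diff(object@mz) <= 0))
      msg <- c(msg, "mz must be strictly increasing")
    if (any(object@intensity < 0))
      msg <- c(msg, "intensities must be non-negative")
  }
  if (length(object@sampleId) != 1 || length(object@label) != 1)
    msg <- c(msg, "sampleId and label must be scalars")
  if (length(msg)) msg else TRUE
})

#' Construct a MassSpectrum
#'
#' @param mz,intensity numeric vectors (see [MassSpectrum-class]).
#' @param sampleId sample identifier.
#' @param label optional class tag.
#' @return a [MassSpectrum-class] object.
#' @examples
#' s <- MassSpectrum(c(800, 800.5, 801), c(10, 12, 9), "s1")
#' mz(s)
#' @export
MassSpectrum <- function(mz, intensity, sampleId = "sample",
                         label = NA_character_) {
  new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      sampleId = as.character(sampleId), label = as.character(label))
}

#' @describeIn MassSpectrum-class m/z axis
#' @param x,object a `MassSpectrum`.
#' @export
setMethod("mz", "MassSpectrum", function(x) x@mz)

#' @describeIn MassSpectrum-class intensity trace
#' @export
setMethod("intensity", "MassSpectrum", function(x) x@intensity)

#' @describeIn MassSpectrum-class sample identifier
#' @export
setMethod("sampleIds", "MassSpectrum", function(x) x@sampleId)

#' @describeIn MassSpectrum-class class label
#' @export
setMethod("classLabels", "MassSpectrum", function(x) x@label)

setMethod("show", "MassSpectrum", function(object) {
  cat("MassSpectrum '", object@sampleId, "' (",
      if (is.na(object@label)) "unlabelled" else object@label, ")\n",
      "  ", length(object@mz), " points, m/z ",
      format(object@mz[1]), "-", format(object@mz[length(object@mz)]), "\n",
      sep = "")
})

#' Cohort of spectra on a shared uniform m/z grid
#'
#' A `SummarizedExperiment` with one row per grid m/z point and one column
#' per sample; the single assay `"intensity"` holds interpolated
#' intensities, `rowData(x)$mz` the shared axis (strictly increasing and
#' uniform), and `colData(x)$label` the class labels.
#'
#' @aliases SpectrumGrid
#' @export
setClass("SpectrumGrid", contains = "SummarizedExperiment")

setValidity("SpectrumGrid", function(object) {
  ax <- rowData(object)$mz
  if (is.null(ax)) return("rowData must contain an 'mz' column")
  if (length(ax) > 1) {
    d <- diff(ax)
    if (any(d <= 0)) return("m/z axis must be strictly increasing")
    if (max(d) - min(d) > 1e-9)
      return("m/z axis must be uniform to 1e-9")
  }
  if (is.null(colData(object)$label))
    return("colData must contain a 'label' column")
  if (anyNA(assay(object)))
    return("grid must not contain missing intensities")
  TRUE
})

#' Construct a SpectrumGrid
#'
#' @param axis uniform, strictly increasing m/z values (Da).
#' @param intensity numeric matrix, `length(axis)` rows x samples columns.
#' @param sampleIds character vector of sample ids.
#' @param labels class labels per sample (`NA` allowed).
#' @return a [SpectrumGrid-class].
#' @export
SpectrumGrid <- function(axis, intensity, sampleIds,
                         labels = rep(NA_character_, length(sampleIds))) {
  intensity <- as.matrix(intensity)
  dimnames(intensity) <- list(NULL, sampleIds)
  new("SpectrumGrid", SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(mz = as.numeric(axis)),
    colData = DataFrame(label = as.character(labels), row.names = sampleIds)))
}

#' @describeIn SpectrumGrid-class shared m/z axis
#' @param x a `SpectrumGrid`.
#' @export
setMethod("mz", "SpectrumGrid", function(x) rowData(x)$mz)

#' @describeIn SpectrumGrid-class sample identifiers
#' @export
setMethod("sampleIds", "SpectrumGrid", function(x) colnames(x))

#' @describeIn SpectrumGrid-class class labels
#' @export
setMethod("classLabels", "SpectrumGrid", function(x) colData(x)$label)

#' @describeIn SpectrumGrid-class samples x m/z points matrix
#' @export
setMethod("featureMatrix", "SpectrumGrid", function(x) t(assay(x)))

#' Cohort mean spectrum
#'
#' Arithmetic per-point mean over all samples of a [SpectrumGrid-class],
#' computed over the whole population regardless of class.
#'
#' @slot mz shared m/z axis (Da).
#' @slot intensity mean intensity per axis point.
#' @aliases MeanSpectrum
#' @export
setClass("MeanSpectrum", slots = c(mz = "numeric", intensity = "numeric"))

setValidity("MeanSpectrum", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must have the same length")
  TRUE
})

#' @describeIn MeanSpectrum-class m/z axis
#' @param x,object a `MeanSpectrum`.
#' @export
setMethod("mz", "MeanSpectrum", function(x) x@mz)

#' @describeIn MeanSpectrum-class mean intensities
#' @export
setMethod("intensity", "MeanSpectrum", function(x) x@intensity)

setMethod("show", "MeanSpectrum", function(object) {
  cat("MeanSpectrum over", length(object@mz), "m/z points\n")
})

#' Samples-by-peak-regions intensity table
#'
#' A `SummarizedExperiment` with one row per peak region (labelled by the
#' region's median m/z) and one column per sample.  The assay `"intensity"`
#' holds each sample's aggregated intensity over the region;
#' `rowData` carries `labelMz`, `startMz`, `endMz` (and grid indices plus
#' mean-spectrum magnitude when produced by [binRegions()]);
#' `colData(x)$label` the class labels.  `labelMz` is strictly increasing.
#'
#' @aliases PeakTable
#' @export
setClass("PeakTable", contains = "SummarizedExperiment")

setValidity("PeakTable", function(object) {
  rd <- rowData(object)
  if (is.null(rd$labelMz)) return("rowData must contain 'labelMz'")
  if (nrow(object) == 0) return("a peak table needs at least one peak")
  if (any(diff(rd$labelMz) <= 0))
    return("peak labels (labelMz) must be strictly increasing")
  if (anyNA(assay(object))) return("peak table must not contain missing cells")
  if (is.null(colData(object)$label))
    return("colData must contain a 'label' column")
  TRUE
})

#' Construct a PeakTable
#'
#' @param labelMz strictly increasing median-m/z peak labels (Da).
#' @param intensity matrix of region intensities, peaks x samples.
#' @param sampleIds character vector of sample ids.
#' @param labels class labels per sample.
#' @param regionInfo optional `data.frame` of extra per-region columns
#'   (e.g. `startMz`, `endMz`).
#' @return a [PeakTable-class].
#' @export
PeakTable <- function(labelMz, intensity, sampleIds, labels,
                      regionInfo = NULL) {
  intensity <- as.matrix(intensity)
  dimnames(intensity) <- list(sprintf("%.2f", labelMz), sampleIds)
  rd <- DataFrame(labelMz = as.numeric(labelMz))
  if (!is.null(regionInfo))
    for (nm in setdiff(names(regionInfo), "labelMz"))
      rd[[nm]] <- regionInfo[[nm]]
  new("PeakTable", SummarizedExperiment(
    assays = list(intensity = intensity), rowData = rd,
    colData = DataFrame(label = as.character(labels), row.names = sampleIds)))
}

#' @describeIn PeakTable-class median-m/z peak labels
#' @param x a `PeakTable`.
#' @export
setMethod("mz", "PeakTable", function(x) rowData(x)$labelMz)

#' @describeIn PeakTable-class sample identifiers
#' @export
setMethod("sampleIds", "PeakTable", function(x) colnames(x))

#' @describeIn PeakTable-class class labels
#' @export
setMethod("classLabels", "PeakTable", function(x) colData(x)$label)

#' @describeIn PeakTable-class samples x peaks matrix
#' @export
setMethod("featureMatrix", "PeakTable", function(x) t(assay(x)))

#' @describeIn PeakTable-class per-region metadata
#' @export
setMethod("peakInfo", "PeakTable",
          function(x) as.data.frame(rowData(x)))

#' Cohort manifest
#'
#' Maps spectrum files to sample ids and binary class labels.  Exactly two
#' distinct class names must be present and every sample id unique.
#'
#' @slot entries `data.frame` with columns `path`, `sample_id`, `label`.
#' @slot classNames the two class tags, in first-appearance order.
#' @aliases CohortManifest
#' @export
setClass("CohortManifest",
  slots = c(entries = "data.frame", classNames = "character"))

setValidity("CohortManifest", function(object) {
  e <- object@entries
  if (!all(c("path", "sample_id", "label") %in% names(e)))
    return("entries must have columns path, sample_id, label")
  if (anyDuplicated(e$sample_id)) return("sample ids must be unique")
  if (length(object@classNames) != 2 ||
      anyDuplicated(object@classNames))
    return("exactly two distinct class names are required")
  if (!all(e$label %in% object@classNames))
    return("every label must be one of the two class names")
  if (!all(object@classNames %in% e$label))
    return("both classes must be non-empty")
  TRUE
})

#' @describeIn CohortManifest-class sample identifiers
#' @param x,object a `CohortManifest`.
#' @export
setMethod("sampleIds", "CohortManifest", function(x) x@entries$sample_id)

#' @describeIn CohortManifest-class class labels
#' @export
setMethod("classLabels", "CohortManifest", function(x) x@entries$label)

setMethod("show", "CohortManifest", function(object) {
  tab <- table(object@entries$label)
  cat("CohortManifest:", nrow(object@entries), "samples (",
      paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "), ")\n")
})

setMethod("show", "SpectrumGrid", function(object) {
  ax <- rowData(object)$mz
  cat("SpectrumGrid:", ncol(object), "samples x", nrow(object),
      "m/z points\n  axis", format(ax[1]), "-", format(ax[length(ax)]),
      "Da, step", format(if (length(ax) > 1) ax[2] - ax[1] else NA), "Da\n")
})

setMethod("show", "PeakTable", function(object) {
  lab <- colData(object)$label
  tab <- table(lab, useNA = "no")
  cat("PeakTable:", ncol(object), "samples x", nrow(object), "peak regions\n")
  if (length(tab))
    cat("  classes:", paste(sprintf("%s n=%d", names(tab), tab),
                            collapse = ", "), "\n")
  lm <- rowData(object)$labelMz
  cat("  label m/z", sprintf("%.2f", lm[1]), "-",
      sprintf("%.2f", lm[length(lm)]), "Da\n")
})
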