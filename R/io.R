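# Plain-text I/O: two-column spectrum files, cohort manifests and peak
# tables.  All formats are delimiter-based text so cohorts round-trip
# through version control and across platforms.

.detectSep <- function(line) {
  if (grepl(",", line)) "," else if (grepl("\t", line)) "\t" else ""
}

#' Read a raw spectrum from a two-column delimited file
#'
#' The file holds one (m/z, intensity) pair per row, comma-, tab- or
#' whitespace-separated, with an optional header line.  Rows are sorted by
#' m/z and duplicate m/z values are averaged, so the result always
#' satisfies the [MassSpectrum-class] invariants regardless of input row
#' order.
#'
#' @param path file to read.
#' @param sep field separator; `"auto"` (default) detects comma, tab or
#'   whitespace from the first line.
#' @param sampleId sample id to attach; default the file name without
#'   extension.
#' @param label optional class tag to attach.
#' @return a [MassSpectrum-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("801,5", "800,3"), f)
#' mz(readSpectrum(f))   # sorted: 800 801
#' @export
readSpectrum <- function(path, sep = "auto", sampleId = NULL,
                         label = NA_character_) {
  stopIfNot(file.exists(path), "spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("spectrum file is empty: ", path)
  if (identical(sep, "auto")) sep <- .detectSep(lines[1])
  splitLine <- function(l)
    if (nzchar(sep)) strsplit(l, sep, fixed = TRUE) else strsplit(trimws(l), "[ \t]+")
  fields <- splitLine(lines)
  firstLine <- 1L
  suppressWarnings(
    if (anyNA(as.numeric(trimws(fields[[1]])))) firstLine <- 2L)  # header
  fields <- fields[seq(firstLine, length(fields))]
  nf <- lengths(fields)
  if (any(nf != 2))
    stop("malformed row at line ", which(nf != 2)[1] + firstLine - 1L,
         " of ", path, ": expected 2 fields")
  suppressWarnings({
    m <- as.numeric(trimws(vapply(fields, `[`, "", 1L)))
    i <- as.numeric(trimws(vapply(fields, `[`, "", 2L)))
  })
  bad <- which(is.na(m) | is.na(i))
  if (length(bad))
    stop("malformed row at line ", bad[1] + firstLine - 1L, " of ", path,
         ": non-numeric value")
  if (anyDuplicated(m)) {
    grp <- factor(m, levels = unique(sort(m)))
    i <- as.numeric(tapply(i, grp, mean))
    m <- as.numeric(levels(grp))
  } else {
    ord <- order(m)
    m <- m[ord]; i <- i[ord]
  }
  if (length(m) < 2)
    stop("degenerate spectrum (fewer than 2 distinct m/z points): ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  MassSpectrum(m, i, sampleId = sampleId, label = label)
}

#' Write a spectrum as two-column CSV
#'
#' @param spectrum a [MassSpectrum-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopIfNot(is(spectrum, "MassSpectrum"), "'spectrum' must be a MassSpectrum")
  write.csv(data.frame(mz = spectrum@mz, intensity = spectrum@intensity),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with header `path,sample_id,label` mapping spectrum
#' files to sample ids and class labels.  Exactly two distinct labels must
#' be present and sample ids must be unique.
#'
#' @param path manifest file.
#' @return a [CohortManifest-class]; its `classNames` are the two labels in
#'   first-appearance order.
#' @export
readManifest <- function(path) {
  stopIfNot(file.exists(path), "manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopIfNot(all(c("path", "sample_id", "label") %in% names(df)),
            "manifest must have columns path, sample_id, label")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest: ",
         df$sample_id[anyDuplicated(df$sample_id)])
  cn <- unique(df$label)
  if (length(cn) != 2)
    stop("manifest must contain exactly 2 classes, found ", length(cn),
         ": ", paste(cn, collapse = ", "))
  new("CohortManifest", entries = df[c("path", "sample_id", "label")],
      classNames = cn)
}

#' Write a cohort manifest
#'
#' @param manifest a [CohortManifest-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest@entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load all spectra listed in a manifest
#'
#' @param manifest a [CohortManifest-class].
#' @param baseDir directory that relative paths in the manifest are
#'   resolved against (default: current directory).
#' @return list of [MassSpectrum-class] objects with labels attached.
#' @export
loadCohort <- function(manifest, baseDir = ".") {
  e <- manifest@entries
  lapply(seq_len(nrow(e)), function(k) {
    p <- e$path[k]
    if (!file.exists(p)) p <- file.path(baseDir, e$path[k])
    readSpectrum(p, sampleId = e$sample_id[k], label = e$label[k])
  })
}

#' Write a peak table as CSV
#'
#' Layout: first column `sample_id`, second `label`, remaining columns one
#' per peak region named by the region's median m/z rendered at 2 decimal
#' places; one row per sample with the region mean intensities at full
#' precision.  [readPeakTable()] round-trips this format (matrix equal to
#' 1e-9).
#'
#' @param table a [PeakTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(table, path) {
  stopIfNot(is(table, "PeakTable"), "'table' must be a PeakTable")
  stopIfNot(nrow(table) > 0, "refusing to write an empty peak table")
  m <- featureMatrix(table)                    # samples x peaks
  df <- data.frame(sample_id = sampleIds(table),
                   label = classLabels(table),
                   m, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("%.2f", mz(table))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write peak table to ", path)
  on.exit(close(con))
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak table from CSV
#'
#' Expects the layout written by [writePeakTable()]: columns
#' `sample_id,label,<m/z>,<m/z>,...` with strictly increasing numeric peak
#' labels.
#'
#' @param path file to read.
#' @return a [PeakTable-class].
#' @export
readPeakTable <- function(path) {
  stopIfNot(file.exists(path), "peak table not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(identical(names(df)[1:2], c("sample_id", "label")),
            "peak table must start with columns sample_id,label")
  stopIfNot(ncol(df) > 2, "peak table has no peak columns")
  labs <- suppressWarnings(as.numeric(names(df)[-(1:2)]))
  if (anyNA(labs) || any(diff(labs) <= 0))
    stop("peak column labels must be strictly increasing numeric m/z values")
  m <- as.matrix(df[-(1:2)])
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing cell in peak table at row ", idx[1], ", column '",
         names(df)[-(1:2)][idx[2]], "'")
  }
  mode(m) <- "numeric"
  PeakTable(labelMz = labs, intensity = t(m),
            sampleIds = df$sample_id, labels = df$label)
}

#' Write a peak-region report as CSV
#'
#' @param regions region `data.frame` from [detectPeakRegions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRegions <- function(regions, path) {
  write.csv(regions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
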