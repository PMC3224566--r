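# Synthetic two-class MALDI-TOF cohorts with known differential peaks.
# Each spectrum is an exponentially decaying matrix baseline plus Gaussian
# peptide peaks plus i.i.d. additive noise, with per-sample rigid mass
# drift and per-peak log-normal intensity scatter; a configured subset of
# peaks carries a class-conditional fold change.

#' Simulation configuration
#'
#' Defaults emulate a serum-profiling study design: 99 samples in two
#' nearly balanced classes over m/z 800-3500 Da with 10 differential peaks
#' at threefold change.
#'
#' @param nPerClass two sample counts, one per class.
#' @param mzRange spectrum support (lo, hi) in Da.
#' @param gridStep native sampling step of the simulated instrument (Da).
#' @param nPeaks number of Gaussian peptide peaks.
#' @param nInformative number of peaks carrying a class fold change
#'   (must not exceed `nPeaks`).
#' @param foldChange multiplicative class effect at informative peaks;
#'   applied as `foldChange` or `1/foldChange` alternately so markers go in
#'   both directions.
#' @param baselineScale amplitude of the exponential-decay matrix baseline
#'   at the low-m/z end (0 disables it).
#' @param noiseSd standard deviation of additive i.i.d. noise.
#' @param driftSd standard deviation of the rigid per-sample m/z shift (Da).
#' @param intensityCv coefficient of variation of the per-sample, per-peak
#'   log-normal amplitude scatter.
#' @param widthRange Gaussian sigma (Da) at the low and high end of the m/z
#'   range; widths interpolate linearly in between (peaks broaden with
#'   mass).
#' @param amplitudeRange base peak amplitudes are drawn uniformly from this
#'   range.
#' @param classNames the two class tags; the second is the positive class
#'   that receives the fold change.
#' @param seed master seed; every draw in the generator derives from it.
#' @return a `SimConfig` (validated list).
#' @export
simConfig <- function(nPerClass = c(49, 50), mzRange = c(800, 3500),
                      gridStep = 0.05, nPeaks = 60, nInformative = 10,
                      foldChange = 3, baselineScale = 30, noiseSd = 2,
                      driftSd = 0.05, intensityCv = 0.15,
                      widthRange = c(0.4, 1.2), amplitudeRange = c(80, 250),
                      classNames = c("ctrl", "case"), seed = 1) {
  cfg <- list(nPerClass = as.integer(nPerClass), mzRange = as.numeric(mzRange),
              gridStep = gridStep, nPeaks = as.integer(nPeaks),
              nInformative = as.integer(nInformative), foldChange = foldChange,
              baselineScale = baselineScale, noiseSd = noiseSd,
              driftSd = driftSd, intensityCv = intensityCv,
              widthRange = as.numeric(widthRange),
              amplitudeRange = as.numeric(amplitudeRange),
              classNames = as.character(classNames), seed = as.integer(seed))
  stopIfNot(length(cfg$nPerClass) == 2 && all(cfg$nPerClass >= 0),
            "nPerClass must be two non-negative counts")
  stopIfNot(cfg$mzRange[1] < cfg$mzRange[2], "mzRange must satisfy lo < hi")
  stopIfNot(cfg$gridStep > 0, "gridStep must be positive")
  stopIfNot(cfg$nInformative <= cfg$nPeaks,
            "nInformative must not exceed nPeaks")
  stopIfNot(cfg$foldChange > 0, "foldChange must be positive")
  stopIfNot(all(c(cfg$baselineScale, cfg$noiseSd, cfg$driftSd,
                  cfg$intensityCv) >= 0), "all scales must be >= 0")
  stopIfNot(all(cfg$widthRange > 0) && all(cfg$amplitudeRange > 0),
            "widths and amplitudes must be positive")
  stopIfNot(length(cfg$classNames) == 2 &&
              !anyDuplicated(cfg$classNames),
            "classNames must be two distinct tags")
  class(cfg) <- c("SimConfig", "list")
  cfg
}

.peakWidth <- function(loc, cfg) {
  f <- (loc - cfg$mzRange[1]) / diff(cfg$mzRange)
  cfg$widthRange[1] + f * diff(cfg$widthRange)
}

#' Draw the cohort's peak templates and ground truth
#'
#' Peak locations are sampled without replacement on the native grid with a
#' minimum separation of 6 sigma (of the wider neighbour), so peaks stay
#' resolvable; widths grow linearly with m/z; exactly `nInformative`
#' templates receive a fold change different from 1.
#'
#' @param config a [simConfig()].
#' @return list with `templates` (`data.frame`: location, width, amplitude,
#'   foldChange) sorted by location, and `truth` (list with
#'   `informativeLocations` and named `foldChanges`).
#' @export
makeTemplates <- function(config) {
  cfg <- config
  if (cfg$nPeaks == 0)
    return(list(templates = data.frame(location = numeric(), width = numeric(),
                                       amplitude = numeric(),
                                       foldChange = numeric()),
                truth = list(informativeLocations = numeric(),
                             foldChanges = numeric())))
  lo <- cfg$mzRange[1]; hi <- cfg$mzRange[2]
  maxw <- max(cfg$widthRange)
  if (cfg$nPeaks * 6 * maxw > (hi - lo))
    stop("infeasible config: m/z range too small for ", cfg$nPeaks,
         " peaks at >= 6-sigma separation")
  margin <- 6 * maxw
  withSeed(cfg$seed, {
    grid <- seq(lo + margin, hi - margin, by = cfg$gridStep)
    loc <- numeric(0)
    tries <- 0L
    while (length(loc) < cfg$nPeaks) {
      cand <- grid[sample.int(length(grid), 1)]
      sep <- 6 * pmax(.peakWidth(cand, cfg), .peakWidth(loc, cfg))
      if (!length(loc) || all(abs(cand - loc) >= sep))
        loc <- c(loc, cand)
      tries <- tries + 1L
      if (tries > 10000L * cfg$nPeaks)
        stop("infeasible config: could not place ", cfg$nPeaks,
             " peaks at >= 6-sigma separation")
    }
    loc <- sort(loc)
    tmpl <- data.frame(location = loc,
                       width = .peakWidth(loc, cfg),
                       amplitude = runif(cfg$nPeaks, cfg$amplitudeRange[1],
                                         cfg$amplitudeRange[2]),
                       foldChange = 1)
    if (cfg$nInformative > 0) {
      inf <- sort(sample.int(cfg$nPeaks, cfg$nInformative))
      # alternate up/down so the panel carries markers in both directions
      updown <- rep_len(c(cfg$foldChange, 1 / cfg$foldChange),
                        cfg$nInformative)
      tmpl$foldChange[inf] <- updown
    } else inf <- integer(0)
    list(templates = tmpl,
         truth = list(informativeLocations = tmpl$location[inf],
                      foldChanges = setNames(tmpl$foldChange[inf],
                                             sprintf("%.2f", tmpl$location[inf]))))
  })
}

.baseline <- function(mzv, cfg)
  cfg$baselineScale * exp(-(mzv - cfg$mzRange[1]) / 1000)

#' Synthesize one spectrum
#'
#' Intensity model per m/z point m:
#' `baseline(m) + sum_p a_p exp(-(m - loc_p - delta)^2 / (2 sigma_p^2)) + eps`,
#' where `a_p` is the template amplitude times the class fold change (for
#' the positive class) times a per-sample log-normal factor with
#' coefficient of variation `intensityCv`; `delta` is one rigid
#' N(0, driftSd) m/z shift per sample and `eps` i.i.d. N(0, noiseSd) noise.
#' Intensities are clipped at 0.
#'
#' @param templates templates from [makeTemplates()].
#' @param classTag class label of the sample.
#' @param config the [simConfig()].
#' @param sampleSeed per-sample seed (same seed, same spectrum).
#' @param sampleId sample identifier.
#' @return a [MassSpectrum-class].
#' @export
synthesizeSpectrum <- function(templates, classTag, config, sampleSeed,
                               sampleId = "sample") {
  cfg <- config
  axis <- seq(cfg$mzRange[1], cfg$mzRange[2], by = cfg$gridStep)
  withSeed(sampleSeed, {
    y <- .baseline(axis, cfg)
    np <- nrow(templates)
    delta <- if (cfg$driftSd > 0) rnorm(1, 0, cfg$driftSd) else 0
    if (np > 0) {
      sdlog <- sqrt(log(1 + cfg$intensityCv^2))
      fac <- if (cfg$intensityCv > 0)
        rlnorm(np, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, np)
      positive <- identical(classTag, cfg$classNames[2])
      for (p in seq_len(np)) {
        a <- templates$amplitude[p] * fac[p]
        if (positive) a <- a * templates$foldChange[p]
        ctr <- templates$location[p] + delta
        w <- templates$width[p]
        lo <- max(1L, ceiling((ctr - 8 * w - axis[1]) / cfg$gridStep) + 1L)
        hi <- min(length(axis),
                  floor((ctr + 8 * w - axis[1]) / cfg$gridStep) + 1L)
        if (lo > hi) next
        win <- lo:hi
        y[win] <- y[win] + a * exp(-(axis[win] - ctr)^2 / (2 * w^2))
      }
    }
    if (cfg$noiseSd > 0) y <- y + rnorm(length(axis), 0, cfg$noiseSd)
    y <- pmax(y, 0)
    MassSpectrum(axis, y, sampleId = sampleId, label = classTag)
  })
}

#' Generate a labelled synthetic cohort
#'
#' @param config a [simConfig()].
#' @return list of class `SyntheticCohort` with `spectra` (list of
#'   [MassSpectrum-class], labels balanced per `nPerClass`), `templates`,
#'   and `truth` (the planted informative peak locations and fold changes).
#' @examples
#' cfg <- simConfig(nPerClass = c(3, 3), nPeaks = 5, nInformative = 2,
#'                  noiseSd = 0.5, seed = 7)
#' coh <- generateCohort(cfg)
#' length(coh$spectra)
#' @export
generateCohort <- function(config) {
  cfg <- config
  tt <- makeTemplates(cfg)
  n <- sum(cfg$nPerClass)
  tags <- rep(cfg$classNames, times = cfg$nPerClass)
  ids <- sprintf("%s_%03d", tags, unlist(lapply(cfg$nPerClass, seq_len)))
  seeds <- deriveSeeds(cfg$seed + 1L, max(n, 1))
  spectra <- lapply(seq_len(n), function(k)
    synthesizeSpectrum(tt$templates, tags[k], cfg, seeds[k], sampleId = ids[k]))
  structure(list(spectra = spectra, templates = tt$templates,
                 truth = tt$truth, config = cfg),
            class = c("SyntheticCohort", "list"))
}

#' Write a synthetic cohort to disk
#'
#' Emits one two-column CSV per spectrum, a cohort manifest, and the ground
#' truth as YAML.
#'
#' @param cohort a [generateCohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- data.frame(path = character(), sample_id = character(),
                  label = character())
  for (sp in cohort$spectra) {
    f <- file.path(dir, paste0(sp@sampleId, ".csv"))
    writeSpectrum(sp, f)
    e <- rbind(e, data.frame(path = basename(f), sample_id = sp@sampleId,
                             label = sp@label))
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(e, mpath, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    informative_locations = as.numeric(cohort$truth$informativeLocations),
    fold_changes = as.list(cohort$truth$foldChanges)),
    file.path(dir, "ground_truth.yaml"))
  invisible(mpath)
}
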