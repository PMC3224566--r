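# Orchestration: simulate (or load) -> preprocess -> blind split -> GANN
# reduction -> stepwise ranking -> ensemble blind evaluation, with one
# master seed, a hard blind-leakage guard and per-stage artifacts.

#' Assemble a pipeline configuration
#'
#' Builds the nested configuration for [runPipeline()], merging
#' user-supplied values over desk-scale defaults.  Stage seeds derive
#' deterministically from the master seed (seed + stage ordinal).
#'
#' @param seed master seed.
#' @param outDir optional output directory; when set, every stage writes
#'   its table as CSV for diffing.
#' @param sim list of [simConfig()] overrides (set `manifest` instead to
#'   load real spectra from disk).
#' @param preprocess list: `gridStep`, `smoothWindow`, `cropRange`,
#'   `boundary` ([boundaryParams()] overrides), `aggregate`.
#' @param split list: `ratio` (train fraction, default 0.7).
#' @param gann list of [gannParams()] overrides plus `topM` (focused
#'   subset size, default 20 at desk scale).
#' @param stepwise list of [stepwiseParams()] overrides.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(seed = 1, outDir = NULL, sim = list(),
                           preprocess = list(), split = list(),
                           gann = list(), stepwise = list()) {
  pp <- modifyList(list(gridStep = 0.05, smoothWindow = 0.2,
                        cropRange = c(800, 3500), boundary = list(),
                        aggregate = "mean"), preprocess)
  cfg <- list(
    seed = as.integer(seed), outDir = outDir,
    sim = sim,
    preprocess = pp,
    split = modifyList(list(ratio = 0.7), split),
    gann = modifyList(list(nRuns = 10, evaluationBudget = 10000,
                           topM = 20), gann),
    stepwise = stepwise)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The file may define any subset of the [pipelineConfig()] sections; a
#' top-level `seed` field is required.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  stopIfNot(!is.null(y$seed), "pipeline config must define a seed")
  do.call(pipelineConfig, y[intersect(names(y),
    c("seed", "outDir", "sim", "preprocess", "split", "gann", "stepwise"))])
}

# Hard guard: no blind sample id may ever reach a fitting stage.
checkNoLeakage <- function(trainIds, blindIds) {
  bad <- intersect(trainIds, blindIds)
  if (length(bad))
    stop("blind-set leakage: sample(s) ", paste(bad, collapse = ", "),
         " present in a training table", call. = FALSE)
  invisible(TRUE)
}

#' Run the full marker-discovery pipeline
#'
#' Stages, in order: cohort simulation (or loading via a manifest),
#' preprocessing of all spectra into a peak table, stratified 70:30
#' train/blind split, GANN feature reduction on the training samples only,
#' forward stepwise ranking of the focused peaks, final ensemble fit and
#' blind-set prediction.  Blind sample ids are recorded at split time and
#' asserted absent from every fitting call.
#'
#' @param config a [pipelineConfig()] (or [readPipelineConfig()]) result.
#' @return a `RunReport` list: `panel`, `predictions`, `accuracy` (percent
#'   correct on the blind set), `auc`, `rates`, `ranking`, `regions`,
#'   `recovery` (planted-marker bookkeeping for synthetic cohorts),
#'   `timings` (seconds per stage), `blindIds`, `artifacts` (paths and
#'   md5 digests when `outDir` is set), and the echoed `config`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  # -- simulate / load ------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim$manifest)) {
    man <- readManifest(config$sim$manifest)
    spectra <- loadCohort(man, baseDir = dirname(config$sim$manifest))
  } else {
    simCfg <- do.call(simConfig, modifyList(config$sim,
                                            list(seed = config$seed + 1L)))
    cohort <- generateCohort(simCfg)
    spectra <- cohort$spectra
    truth <- cohort$truth
  }
  tick("simulate")

  # -- preprocess -----------------------------------------------------
  pp <- config$preprocess
  prep <- preprocessCohort(spectra, gridStep = pp$gridStep,
                           smoothWindow = pp$smoothWindow,
                           cropRange = pp$cropRange,
                           params = do.call(boundaryParams, pp$boundary),
                           aggregate = pp$aggregate)
  peaks <- prep$peakTable
  tick("preprocess")

  # -- blind split ----------------------------------------------------
  sp <- splitTrainBlind(peaks, ratio = config$split$ratio,
                        seed = config$seed + 3L)
  blindIds <- sampleIds(sp$blind)
  tick("split")

  # -- GANN reduction (training samples only) -------------------------
  checkNoLeakage(sampleIds(sp$train), blindIds)
  gOver <- config$gann
  topM <- gOver$topM %||% 20
  gPar <- do.call(gannParams, modifyList(
    gOver[setdiff(names(gOver), "topM")], list(seed = config$seed + 4L)))
  red <- reduceFeatures(sp$train, gPar, topM = topM)
  focusedTrain <- red$focused
  focusedBlind <- sp$blind[red$ranking$topFeatures, ]
  tick("gann")

  # -- stepwise ranking -----------------------------------------------
  checkNoLeakage(sampleIds(focusedTrain), blindIds)
  sPar <- do.call(stepwiseParams, modifyList(
    config$stepwise, list(seed = config$seed + 5L)))
  panel <- stepwiseRank(focusedTrain, sPar)
  tick("stepwise")

  # -- final ensemble + blind evaluation ------------------------------
  checkNoLeakage(sampleIds(focusedTrain), blindIds)
  ens <- fitFinalEnsemble(focusedTrain, panel, sPar)
  preds <- ensemblePredict(ens, focusedBlind)
  accuracy <- 100 * mean(preds$correct)
  roc <- rocAuc(preds$output, preds$target, positive = ens$classNames[2])
  rates <- confusionRates(preds$predicted, preds$target)
  tick("evaluate")

  recovery <- NULL
  if (!is.null(truth) && length(truth$informativeLocations)) {
    loc <- truth$informativeLocations
    reg <- prep$regions
    inRegion <- vapply(loc, function(l)
      any(reg$startMz <= l & reg$endMz >= l), TRUE)
    panelHits <- vapply(panel$ion, function(ion)
      any(reg$startMz[match(ion, reg$labelMz)] <= loc &
            reg$endMz[match(ion, reg$labelMz)] >= loc), TRUE)
    recovery <- list(informativeLocations = loc,
                     detectedAsRegion = inRegion,
                     panelIsPlanted = panelHits,
                     nPlantedInPanel = sum(panelHits))
  }

  artifacts <- NULL
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      peaks = writePeakTable(peaks, file.path(config$outDir, "peaks.csv")),
      regions = writeRegions(prep$regions,
                             file.path(config$outDir, "regions.csv")),
      ranking = {
        f <- file.path(config$outDir, "gann_ranking.csv")
        write.csv(red$ranking$ranking, f, row.names = FALSE); f
      },
      panel = {
        f <- file.path(config$outDir, "panel.csv")
        write.csv(as.data.frame(panel), f, row.names = FALSE); f
      },
      predictions = {
        f <- file.path(config$outDir, "predictions.csv")
        write.csv(as.data.frame(preds), f, row.names = FALSE); f
      })
    artifacts <- data.frame(stage = names(paths), path = unname(paths),
                            md5 = unname(tools::md5sum(unname(paths))))
  }

  structure(list(panel = panel, predictions = preds, accuracy = accuracy,
                 auc = roc$auc, roc = roc, rates = rates,
                 ranking = red$ranking, regions = prep$regions,
                 recovery = recovery, truth = truth,
                 blindIds = blindIds, timings = unlist(timings),
                 artifacts = artifacts, config = config),
            class = c("RunReport", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.RunReport <- function(x, ...) {
  cat("Marker-discovery run report\n")
  cat("  peak regions detected: ", nrow(x$regions), "\n", sep = "")
  cat("  panel: ", nrow(x$panel), " ions (",
      paste(sprintf("%.2f", x$panel$ion), collapse = ", "), ")\n", sep = "")
  cat(sprintf("  blind accuracy: %.2f%% (n=%d), AUC %.3f\n",
              x$accuracy, nrow(x$predictions), x$auc))
  if (!is.null(x$recovery))
    cat("  planted markers in panel: ", x$recovery$nPlantedInPanel, "/",
        length(x$recovery$informativeLocations), "\n", sep = "")
  invisible(x)
}
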