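# Hybrid genetic-algorithm / feedforward-network feature reducer.  Each
# chromosome carries 20 feature genes in [0,1) (decoded to peak indices)
# plus the 48 weights of a 20-2-2 tanh network in [-1,1]; fitness is the
# number of correctly argmax-classified training samples.  A steady-state
# GA (tournament selection, single-point crossover, uniform-resample
# mutation, N-1 elitism) runs until an evaluation budget is spent.

#' GANN parameters
#'
#' @param populationSize GA population size (default 300).
#' @param chromFeatures feature genes per chromosome (default 20).
#' @param tournamentSize tournament size for parent selection (default 2).
#' @param pCrossover single-point crossover probability (default 0.5).
#' @param pMutation per-gene uniform-resample mutation probability
#'   (default 0.1).
#' @param evaluationBudget fitness evaluations per run (default 80000).
#' @param nRuns independent repeats of the whole cycle whose best subsets
#'   are tallied by [aggregateRuns()] (default 50; large screens may use
#'   many more).
#' @param hiddenUnits,outputUnits network architecture (default 2 and 2:
#'   a 20-2-2 net, 48 weights including the 4 bias blocks).
#' @param seed master seed.
#' @return a `GannParams` (validated list).
#' @export
gannParams <- function(populationSize = 300, chromFeatures = 20,
                       tournamentSize = 2, pCrossover = 0.5,
                       pMutation = 0.1, evaluationBudget = 80000,
                       nRuns = 50, hiddenUnits = 2, outputUnits = 2,
                       seed = 1) {
  p <- list(populationSize = as.integer(populationSize),
            chromFeatures = as.integer(chromFeatures),
            tournamentSize = as.integer(tournamentSize),
            pCrossover = pCrossover, pMutation = pMutation,
            evaluationBudget = as.integer(evaluationBudget),
            nRuns = as.integer(nRuns), hiddenUnits = as.integer(hiddenUnits),
            outputUnits = as.integer(outputUnits), seed = as.integer(seed))
  stopIfNot(p$pCrossover >= 0 && p$pCrossover <= 1 &&
              p$pMutation >= 0 && p$pMutation <= 1,
            "probabilities must lie in [0, 1]")
  stopIfNot(p$populationSize >= p$tournamentSize,
            "population must be at least the tournament size")
  stopIfNot(p$evaluationBudget >= p$populationSize,
            "evaluation budget must cover the initial population")
  class(p) <- c("GannParams", "list")
  p
}

#' Decode feature genes to peak indices
#'
#' Gene g in [0,1) maps to 1-based index `floor(g * nFeatures) + 1`,
#' clamped to `nFeatures`; duplicates are permitted.
#'
#' @param genes numeric vector of feature genes in [0,1).
#' @param nFeatures number of available features.
#' @return integer indices in 1..nFeatures.
#' @examples
#' decodeFeatures(c(0, 0.5, 0.999999), 2560)   # 1 1281 2560
#' @export
decodeFeatures <- function(genes, nFeatures) {
  stopIfNot(nFeatures >= 1, "nFeatures must be >= 1")
  pmin(as.integer(floor(genes * nFeatures)), nFeatures - 1L) + 1L
}

#' Reference forward pass of the chromosome-encoded network
#'
#' Pure-R evaluation of the 20-2-2 tanh network whose weights live on a
#' chromosome (hidden-layer blocks of `length(x)+1` weights per hidden
#' unit, bias last, followed by output blocks of `hiddenUnits+1` weights).
#' Used as the independent cross-check of the compiled GA fitness path.
#'
#' @param weights weight genes (48 for a 20-2-2 net).
#' @param x input feature values (standardized).
#' @param hiddenUnits,outputUnits architecture (defaults 2, 2).
#' @return numeric vector of `outputUnits` tanh activations in (-1, 1).
#' @export
annForward <- function(weights, x, hiddenUnits = 2, outputUnits = 2) {
  nf <- length(x)
  n1 <- (nf + 1) * hiddenUnits
  stopIfNot(length(weights) == n1 + (hiddenUnits + 1) * outputUnits,
            "weight count does not match the architecture")
  W1 <- matrix(weights[seq_len(n1)], nrow = nf + 1)
  W2 <- matrix(weights[-seq_len(n1)], nrow = hiddenUnits + 1)
  h <- tanh(drop(crossprod(W1, c(x, 1))))
  tanh(drop(crossprod(W2, c(h, 1))))
}

#' Classification-count fitness of a chromosome
#'
#' Predicted class is the argmax of the two output activations (tie: first
#' class); fitness is the number of samples whose prediction matches the
#' label.  This R implementation recounts predictions sample by sample and
#' serves as the oracle for the compiled GA path.
#'
#' @param featureGenes,weightGenes the chromosome.
#' @param X standardized samples x features matrix.
#' @param y01 integer labels in \{0, 1\}.
#' @param hiddenUnits,outputUnits architecture.
#' @return integer fitness in 0..nrow(X).
#' @export
gannFitness <- function(featureGenes, weightGenes, X, y01,
                        hiddenUnits = 2, outputUnits = 2) {
  idx <- decodeFeatures(featureGenes, ncol(X))
  correct <- 0L
  for (s in seq_len(nrow(X))) {
    o <- annForward(weightGenes, X[s, idx], hiddenUnits, outputUnits)
    pred <- which.max(o) - 1L            # tie -> class 0
    if (pred == y01[s]) correct <- correct + 1L
  }
  correct
}

#' One GANN run
#'
#' Standardizes the peak table (z-score per feature), runs the
#' steady-state GA until the evaluation budget is spent and returns the
#' run record.
#'
#' @param table a [PeakTable-class] with binary labels, or a list with
#'   elements `X` (samples x features) and `y01`.
#' @param params a [gannParams()].
#' @param seed run seed (default `params$seed`).
#' @return a `GannRun` list: `bestChromosome` (`featureGenes`,
#'   `weightGenes`), `bestFitness`, `bestFeatures` (decoded, unique,
#'   sorted), `trajectory` (per-generation best fitness, non-decreasing),
#'   `selectionCounts` (per-feature tally over the final best subset) and
#'   `evaluations`.
#' @export
runGann <- function(table, params = gannParams(), seed = params$seed) {
  if (is(table, "PeakTable")) {
    X <- featureMatrix(table)
    cn <- inferClassNames(classLabels(table))
    y01 <- codeLabels(classLabels(table), cn)
  } else {
    X <- table$X; y01 <- table$y01
  }
  Xs <- zscoreApply(X, zscoreStats(X))
  res <- gann_run_cpp(Xs, as.integer(y01), params$populationSize,
                      params$chromFeatures, params$hiddenUnits,
                      params$outputUnits, params$pCrossover,
                      params$pMutation, params$tournamentSize,
                      params$evaluationBudget, as.integer(seed))
  idx <- decodeFeatures(res$feature_genes, ncol(X))
  structure(list(
    bestChromosome = list(featureGenes = res$feature_genes,
                          weightGenes = res$weight_genes),
    bestFitness = res$best_fitness,
    bestFeatures = sort(unique(idx)),
    trajectory = res$trajectory,
    selectionCounts = tabulate(idx, nbins = ncol(X)),
    evaluations = res$evaluations,
    featureNames = colnames(X)),
    class = c("GannRun", "list"))
}

#' Tally feature selections over repeated GANN runs
#'
#' A feature's frequency is the number of runs whose final best
#' chromosome's decoded subset contains it; the ranking is by descending
#' frequency with ties broken by ascending feature index, and the focused
#' subset is the top `topM` features.
#'
#' @param runs list of `GannRun` objects.
#' @param topM size of the focused subset (default 100).
#' @return a `FeatureRanking` list: `ranking` (`data.frame` with feature
#'   index, name and frequency, ordered), `topFeatures` (indices of the
#'   focused subset, ascending) and `nRuns`.
#' @export
aggregateRuns <- function(runs, topM = 100) {
  stopIfNot(length(runs) >= 1, "need at least one run")
  p <- length(runs[[1]]$selectionCounts)
  freq <- integer(p)
  for (r in runs) freq <- freq + as.integer(r$selectionCounts > 0)
  ord <- order(-freq, seq_len(p))
  rk <- data.frame(feature = ord,
                   name = if (!is.null(runs[[1]]$featureNames))
                     runs[[1]]$featureNames[ord] else as.character(ord),
                   frequency = freq[ord])
  structure(list(ranking = rk,
                 topFeatures = sort(ord[seq_len(min(topM, p))]),
                 nRuns = length(runs)),
            class = c("FeatureRanking", "list"))
}

#' GANN data reduction: repeated runs plus aggregation
#'
#' Runs `params$nRuns` independent GANN cycles (seeds derived from
#' `params$seed`) and subsets the table to the focused top-`topM` peak set.
#'
#' @param table a [PeakTable-class] with binary labels.
#' @param params a [gannParams()].
#' @param topM focused subset size (default 100).
#' @return list with `focused` (the reduced [PeakTable-class], peak order
#'   preserved), `ranking` (the [aggregateRuns()] result) and `runs`.
#' @export
reduceFeatures <- function(table, params = gannParams(), topM = 100) {
  seeds <- deriveSeeds(params$seed, params$nRuns)
  runs <- lapply(seeds, function(s) runGann(table, params, seed = s))
  rk <- aggregateRuns(runs, topM = topM)
  list(focused = table[rk$topFeatures, ], ranking = rk, runs = runs)
}
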