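# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never disturbs user
# simulations.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# n reproducible integer sub-seeds (< 2^31) derived from one master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

# Largest-remainder apportionment of `total` items across groups with the
# given weights; deterministic (ties go to the earlier group).
apportion <- function(total, weights) {
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  extra <- total - sum(base)
  if (extra > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

# Column z-scoring with statistics from a training partition; constant
# columns get scale 1 so they map to 0 rather than NaN.
zscoreStats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

zscoreApply <- function(X, stats) {
  sweep(sweep(X, 2, stats$center, "-"), 2, stats$scale, "/")
}

# Two-class {0,1} coding of labels against the class-name pair; the second
# class name is the positive class (coded 1).
codeLabels <- function(labels, classNames) {
  if (anyNA(labels)) stop("all samples must be labelled for modelling")
  bad <- setdiff(unique(labels), classNames)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  as.integer(labels == classNames[2])
}

# The two class names of a labelled container, in first-appearance order.
inferClassNames <- function(labels) {
  cn <- unique(labels[!is.na(labels)])
  if (length(cn) != 2)
    stop("exactly two classes are required, found ", length(cn), ": ",
         paste(cn, collapse = ", "))
  cn
}

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
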