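---
title: "Peak-region preprocessing and neural-network marker ranking for MALDI-TOF profiles"
author: "maldiPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-region preprocessing and neural-network marker ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

MALDI-TOF profiling of blood derivatives produces, for every sample, a
trace of relative ion abundance over mass-to-charge (m/z). For tryptic
peptide work the informative window is roughly 800–3500 Da, sampled at a
few hundredths of a dalton, so a cohort is a matrix of ~10^5 columns and
a few dozen rows, with three dominant nuisance structures: a decaying
chemical/matrix baseline, additive detector noise, and per-sample mass
drift that shifts the whole m/z assignment by a small, sample-specific
offset. The goal supported by this package is a short, ranked panel of
candidate marker ions separating two classes, validated on a blind
subset that no fitting step has seen.

# The preprocessing model

The package's preprocessing makes one deliberate simplification: peak
boundaries are defined **once, on the cohort mean spectrum**, and then
applied identically to every sample. Averaging across all samples
(regardless of class) suppresses i.i.d. noise by `1/sqrt(n)` and turns
the shared peak structure into a smooth bump train; in exchange, the
approach is sensitive to gross outlier samples, which should be excluded
upstream.

Concretely, `mergeToGrid()` smooths each spectrum with a centred moving
average (window 0.2 Da — the same pre-filter width classically used when
aligning such data) and interpolates linearly onto a uniform grid.
Linear interpolation was chosen over higher-order polynomial schemes
because it is order-independent, cannot overshoot, and never invents
signal; grid points outside a sample's native support are set to 0 for
the same reason. `cropGrid()` restricts to 800–3500 Da.

`encodeSigns()` writes the mean spectrum as a sequence over {0,1}: 0
when the intensity rises to the next grid point, 1 when it falls *or
ties*. Ties are coded as "not an increase" because a flat stretch cannot
be the ascending flank of a peak; this is the only place the encoding is
asymmetric.

`detectPeakRegions()` scans the sign sequence left to right. A region
opens at the first index of a run of at least `minZeroRun = 3`
consecutive ascents — on real mean spectra a genuine peak flank always
rises for several consecutive points, while noise ripples rarely do. It
closes at the *end* of the first subsequent descent run of length at
least k, so the full descent contributes to the region. Because peaks
broaden with mass (later ions spend longer in the flight tube), k grows
across five m/z checkpoints, 800/1400/1900/2400/3000 Da, with defaults
(3,3,4,4,5); the thresholds are monotone, fully exposed in
`boundaryParams()`, and a region's segment is decided by its start m/z
(half-open, lower-inclusive). Two guards bound pathological regions: a
cap of `maxRegionPoints = 200` grid points (≈ 10 Da at the 0.05 Da
default grid) after which the region is truncated and scanning resumes,
and an optional minimum magnitude (region maximum minus edge minimum of
the mean spectrum), off by default. A region still open at the end of
the axis is closed at the last point. Successive regions are kept
disjoint: a region may not reuse the previous region's closing valley
point.

`binRegions()` turns each region into one feature: the label is the
median m/z of the region's grid points (even counts: mean of the two
central values, which is why labels print at 2 decimals), and the value
for each sample is the mean of that sample's intensities over the
region. A `"max"` aggregator exists for comparison, but maxima equalise
the classes (a single high point dominates regardless of class) and the
mean is the default.

On noisy cohorts this stage intentionally over-segments: ripples on the
mean spectrum produce many shallow regions alongside the true peaks
(thousands of regions from ~50k grid points is typical). That is by
design — boundary recall matters more than precision here, and the two
model-based stages that follow exist precisely to discard uninformative
features.

# GANN reduction

`runGann()` co-evolves a feature subset and a classifier. Each
chromosome holds 20 feature genes in [0,1) (decoded by
`floor(g * p)`, duplicates allowed) and 48 weight genes in [-1,1] — the
weights of a 20-2-2 tanh network including one bias per block
((20+1)×2 + (2+1)×2 = 48). Fitness is the number of correctly
classified training samples under argmax of the two outputs (ties to the
first class). The GA is steady-state: two tournament-of-2 parents
produce two children by single-point crossover (probability 0.5, one cut
point over the concatenated 68 genes) and per-gene uniform-resample
mutation (probability 0.1); the N−1 fittest of population-plus-children
survive together with the fitter child, so the best individual is never
lost and the per-generation best-fitness trajectory is non-decreasing —
a property the test suite asserts on every run. A run stops when the
evaluation budget is spent.

Because fitness saturates once any separating subset is found, a single
run's best subset is a noisy signal. `aggregateRuns()` therefore tallies,
over many independent runs, how often each feature appears in a final
best subset, and keeps the `topM` most-selected features (ties broken by
ascending index for reproducibility). Inputs are z-scored per feature
before entering the network; raw intensities saturate tanh immediately.

# Stepwise ANN ranking

`stepwiseRank()` performs forward selection with small I-2-1
backpropagation networks: at step k every remaining candidate is
appended to the selected set and scored, and the candidate with the
lowest average test MSE wins the step (ties to the lower m/z). Scoring
is Monte-Carlo cross-validation: `nResamples = 50` random stratified
60:20:20 train/test/validation splits; per split, per-pattern gradient
descent (learning rate 0.1, momentum 0.5, shuffled pattern order,
weights initialised uniform [-0.5, 0.5]) for at most 3000 epochs with
early stopping — training halts when the test-partition MSE has not
improved by at least 0.01 within the last 1000 epochs, and the weights
at the best test MSE are kept. The output unit is tanh rescaled to
[0,1] via (tanh+1)/2 so MSE against {0,1} targets and ensemble vote
fractions share one scale. The analytic gradient is verified against
central finite differences to 1e-6 in the test suite.

Two design choices matter for fairness and reproducibility. First, the
same 50 splits and the same per-resample training seeds are reused for
every candidate within an experiment, so candidates are compared on
identical partitions and the ranking cannot depend on the order of the
peak columns. Second, the split sizes follow round-to-nearest with the
remainder to the validation partition (69 samples give 41/14/14, 111
give 67/22/22), apportioned across classes by largest remainder so no
class can vanish from a partition.

The panel length is fixed at `maxSteps = 10`: in practice the test error
flattens (and sometimes drifts up, a mild overfitting signature) after
the first handful of ions, and a fixed-length panel keeps ranking runs
comparable. No outer restart loop is performed around the 10 stepwise
additions; one pass is deterministic given the seed, and repeats belong
at the experiment level if desired.

# Blind evaluation

`splitTrainBlind()` holds out a stratified 30% before any fitting; the
pipeline records the blind sample ids at split time and asserts, before
every fitting call, that none of them appears in a training table — a
leakage bug aborts the run rather than inflating the results.
`fitFinalEnsemble()` trains one network per resample on the full panel;
`ensemblePredict()` lets each sub-model vote (output ≥ 0.5) and reports
the vote fraction for the positive class, the majority call (a 25/25
tie resolves to the positive class, deterministically), and a 95% CI
half-width `2*sqrt(p(1-p)/(n-1))` — the binomial form consistent with
the vote counts. `rocAuc()` sweeps the decision threshold over the
distinct ensemble outputs (samples tied at one output move together);
the trapezoidal area equals the tie-corrected Mann-Whitney statistic,
which the test suite checks on 500 random instances. Per-sample
ensemble outputs are the default ROC input; pooled per-sub-model
decisions can be obtained from the vote matrix attached to the
prediction table.

# The synthetic-data generator

`generateCohort()` emulates what the preprocessing has to survive:
Gaussian peptide peaks (widths growing linearly with m/z, 0.4–1.2 Da
across the window, at least 6 sigma apart so they are resolvable) on an
exponentially decaying matrix baseline, i.i.d. additive noise, one rigid
N(0, driftSd) m/z shift per sample — the simplest model of mass-accuracy
drift through a population — and per-peak log-normal intensity scatter.
A configured subset of peaks carries a class fold change, applied
alternately as f and 1/f so markers go in both directions; intensities
are clipped at 0. The defaults encode the study design the package is
validated against: 49 + 50 samples, m/z 800–3500 at 0.05 Da, 60 peaks
of which 10 are informative at threefold change, noise sd 2 against
amplitudes of 80–250, drift sd 0.05 Da, intensity CV 0.15.

What the generator does *not* model: isotope envelopes, charge states,
detector saturation, m/z-dependent warping, batch effects, or outlier
samples. Passing the recovery tests therefore shows that the chain is
correct and sensitive under realistic noise, drift and scatter — not
that it is robust to every artefact of real instruments.

# Problem sizes and numerical choices

The validation experiments run at a desk scale chosen once: cohorts of
99 samples on a 54k-point grid; GANN at 10 runs × 10,000 evaluations
with a focused subset of 20 peaks for the end-to-end experiments (50
runs and larger subsets for the frequency-ratio experiments); stepwise
at the full 50 resamples. At these sizes one end-to-end run takes on
the order of 1–2 minutes on a single core, and the recovery experiments
repeat it over 10 independent seeds. The GA population (300), operator
rates, the network shapes, the training hyper-parameters and the
60:20:20/70:30 ratios are the classical settings for this workflow and
are not scaled.

Determinism: every stochastic step (simulation, splits, GA, weight
initialisation, pattern shuffling) derives from one master seed; the
compiled code uses its own portable splitmix64 generator so results are
identical across platforms and never disturb R's global RNG state.
Degenerate inputs are errors, not silent results: spectra with fewer
than two points, manifests without exactly two classes, empty peak
tables, crop windows off the axis, single-class AUC.

# Limitations

The mean-spectrum boundary definition shares one weakness with its
motivating workflow: a strong outlier sample distorts the mean and
therefore every region. No baseline subtraction or normalisation is
performed by design; fold changes on a high baseline are attenuated
accordingly. Selection frequencies from few GA runs are coarse
(integer counts), so the focused subset under small run counts is
sensitive to ties; increasing `nRuns` is the remedy. Region labels are
median m/z values of detected regions, so labels shift slightly with
grid step and noise; matching panels across cohorts should use region
overlap, not exact label equality.
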