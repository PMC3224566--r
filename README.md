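# maldiPanel

Differential marker-ion discovery from raw MALDI-TOF mass spectra.

Serum and plasma peptide profiles from MALDI-TOF instruments arrive as
very long (m/z, intensity) traces — tens to hundreds of thousands of
points per sample — contaminated by baseline, electronic and chemical
noise and by per-sample mass drift. Before any ion can be called a
candidate biomarker the cohort has to be reduced to a common
samples × peaks table, and the peaks ranked by how well they separate the
two classes. `maldiPanel` implements a deliberately simple, fully
reproducible version of that workflow for two-class cohorts, aimed at
proteomics groups who want a transparent pre-screen rather than a black
box.

## Method

1. **Peak-region preprocessing.** All spectra are smoothed with a 0.2 Da
   moving average, linearly interpolated onto one uniform m/z grid, and
   cropped to the tryptic-peptide window 800–3500 Da. The cohort **mean
   spectrum** \(\bar{x}_j = \frac{1}{n}\sum_s x_{sj}\) is encoded as a
   binary sign sequence (0 = intensity rises to the next grid point,
   1 = falls or ties). A peak region opens at a run of ≥ 3 consecutive
   ascents and closes at the end of the first descent run of length ≥ k,
   where k rises from 3 to 5 across five m/z checkpoints
   (800/1400/1900/2400/3000 Da) because peaks broaden at high mass. Each
   region becomes one feature, labelled by its median m/z and valued per
   sample by the mean intensity over the region.
2. **GANN reduction.** A steady-state genetic algorithm evolves
   chromosomes carrying 20 feature genes plus the 48 weights of a 20-2-2
   tanh network; fitness is the count of correctly classified training
   samples (Pc = 0.5 single-point crossover, Pm = 0.1 uniform mutation,
   tournament size 2, N−1 elitism, population 300). Features are ranked
   by how many independent runs select them into the final best subset.
3. **Stepwise ANN ranking.** Forward selection with I-2-1
   backpropagation networks (learning rate 0.1, momentum 0.5, ≤ 3000
   epochs, early stopping on test MSE with a 1000-epoch window and 0.01
   threshold) under Monte-Carlo cross-validation: 50 random 60:20:20
   train/test/validation splits per candidate. The ion with the lowest
   average test MSE joins the panel at each step, to a panel of 10.
4. **Blind evaluation.** A stratified 70:30 train/blind split is made
   before any fitting; 50 sub-models (one per resample) vote on each
   blind sample. Reported: vote fractions with 95% CI half-widths
   \(2\sqrt{p(1-p)/(n-1)}\), per-class TPR/FPR, and ROC/AUC by threshold
   sweep.

Because real cohorts of this kind are rarely shareable, the package
includes a seeded synthetic-spectrum generator (Gaussian peptide peaks
over an exponential matrix baseline, additive noise, per-sample mass
drift and log-normal intensity scatter, with a known set of
fold-changed marker peaks) so that every stage can be validated against
ground truth.

## Worked example

```r
library(maldiPanel)
report <- runPipeline(pipelineConfig(seed = 101))
print(report)
```

```
Marker-discovery run report
  peak regions detected: 1616
  panel: 10 ions (2699.20, 1189.68, 1647.45, 1093.95, 949.65, 2078.95,
                  1752.93, 1352.83, 2152.90, 2767.95)
  blind accuracy: 100.00% (n=30), AUC 1.000
  planted markers in panel: 9/10
```

The default configuration simulates a 99-sample two-class cohort
(49 vs 50) with 60 peptide peaks of which 10 carry a threefold class
difference, at moderate noise. Preprocessing finds ~1600 regions (most
are noise ripples on the mean spectrum — exactly what the downstream
reduction is for); the GANN stage (10 runs × 10,000 evaluations here)
focuses the table to 20 peaks, and the stepwise stage ranks a 10-ion
panel in which 9 of the 10 planted markers appear. The 50-sub-model
ensemble classifies all 30 held-out blind samples correctly
(accuracy 100%, AUC 1.0). `report$panel` holds the rank table (ion m/z,
region bounds, average train/test/validation errors per step) and
`report$predictions` the per-sample vote table.

A command-line front end with `simulate` / `preprocess` / `reduce` /
`rank` / `run` subcommands is installed at `inst/cli/maldipeaks.R`.

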