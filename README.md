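# TOCSYprofiler

Open-set metabolite classification for 2D ^1H-^1H TOCSY cross-peak
tables, built for monitoring the metabolic evolution of mesenchymal stem
cells through cultivation and adipogenic/osteogenic differentiation.

A TOCSY spectrum resolves each metabolite into cross peaks at (F2, F1)
frequency coordinates (Hz). Between samples, peaks drift (pH and ionic
strength), metabolites disappear, and new ones appear. Given a single
annotated reference sample, `TOCSYprofiler` must therefore solve two
problems at once for every test peak:

* assign it to a known metabolite despite frequency drift
  (multi-class classification), or
* flag it `NOVEL` when no training metabolite explains it
  (novelty detection).

## Method

Training data are simulated around the reference peak list: each peak is
replicated with independent uniform per-axis shifts up to ±30 Hz (4000
instances, classes balanced by round-robin allocation and under-sampling
of metabolites with more than two multiplets). Two classifiers are
fitted to the (F2, F1) features:

* **KNFST** (Kernel Null Foley–Sammon Transform): a kernel projection ω
  with zero within-class scatter and positive between-class scatter,

  ωᵀ S_w^φ ω = 0  and  ωᵀ S_b^φ ω > 0,

  so each known class collapses onto one target point. Prediction is by
  the nearest target; the minimum target distance is the novelty score
  (novel-if-large).
* **KDE** (Parzen-window classifier): per-class densities
  p(x) = (1/N) Σᵢ (1/h^d) k((x − xᵢ)/h) with a Gaussian profile and a
  leave-one-out-selected global bandwidth. Prediction is by the largest
  class-conditional density, which is also the novelty score
  (novel-if-small).

Novelty thresholds are selected on a Gaussian-noise validation set
(known scores) combined with uniform pseudo-novel draws over the
spectral window, minimizing the validation error. Performance is
summarized by the open-set rates

* false negative rate = 100·Fn/Nn (novel taken as known),
* false positive rate = 100·Fp/(N−Nn) (known flagged novel),
* total error = 100·(Fn+Fe+Fp)/N (Fe: mislabeled known peaks).

The package ships the reference cross-peak table (85 peaks, 32
metabolites, four samples: `ct_d4`, `ct_d14`, `at_d14`, `os_d14`, with
"NP" absence markers preserved) and a synthetic peak-table generator
for controlled benchmarks. The methods vignette
(`vignettes/metabolic-profiling.Rmd`) documents the model, the defaults
and the geometric limits of the bundled table.

## Worked example

```r
library(TOCSYprofiler)

tab <- loadReferenceTable()
tab
#> PeakTable with 85 cross peaks, 32 metabolites
#> samples: ct_d4, ct_d14, at_d14, os_d14
#> peaks per sample: ct_d4=69, ct_d14=76, at_d14=83, os_d14=58

## metabolites appearing during osteogenic differentiation
novelLabels(extractSample(tab, "ct_d4"), extractSample(tab, "os_d14"))
#> [1] "FAT 2" "MI"    "Tau"

## full experiment: augment ct_d4, fit both classifiers, evaluate
rep <- runExperiment(experimentConfig(
  augmentation = augmentationConfig(nTotal = 4000, seed = 1)))
rep@metrics[["os_d14.kde"]]
#> NoveltyMetrics: N=58 (novel 6) | Fn=1 Fp=7 Fe=3
#> false negative rate 16.7% | false positive rate 13.5% | total error 19.0%
```

The counts read: of the 58 osteogenic-sample peaks, 6 belong to
metabolites unseen in the reference; one of those was absorbed into a
known class (a myo-inositol multiplet that sits inside the
glycerophosphocholine training cloud), 7 known peaks scored outside the
acceptance region and were flagged novel (tyrosine drifts up to ~85 Hz
from its training position), and 3 known peaks were assigned a
neighboring metabolite in the crowded region (this run: Glu taken for
Met, whose multiplets lie 6 Hz apart, Tyr for pEtN, Thr for Leu). The
vignette quantifies why these overlaps are intrinsic to the printed
frequency table and bound the achievable error rates from below.

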