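# mobidt

Analysis pipeline for **dual-task mobile brain/body imaging (MoBI)**
experiments: a Go/NoGo response inhibition task performed while sitting or
walking on a treadmill, with synchronized behavior, 3D gait kinematics and
64-channel EEG. The package is aimed at cognitive-neurophysiology analysts
who need the full chain — behavioral scoring, gait variability, ERP
preprocessing, spatiotemporal cluster statistics and combined
false-discovery-rate control — as tested, reusable functions rather than
one-off scripts.

## What it computes

* **Behavior** — responses earlier than 183 ms post-stimulus are discarded
  as delayed responses to the previous trial; trials are classified as
  hit / miss / correct rejection / false alarm; sensitivity is the
  signal-detection index `d' = qnorm(HR) - qnorm(FAR)` (log-linear edge
  correction at perfect rates), with mean Go RT alongside. Participants
  whose walking-minus-sitting `d'` difference exceeds the cohort-null 95%
  bound (`1.96 x SD` of the cohort's differences) are classified improvers
  (IMP); everyone else, including significant decliners, non-improvers
  (nIMP).
* **Gait** — heel strikes are prominence-filtered local maxima (> 0.1 m) of
  the fore-aft heel position; gait cycles between consecutive same-foot
  strikes are kurtosis-screened, resampled to 100 points and compared
  stride-to-stride by dynamic time warping (3D Euclidean cost, symmetric
  steps, unnormalized); the pooled mean DTW distance is the stride-to-stride
  variability measure.
* **EEG** — zero-phase Chebyshev Type II filtering, anti-aliased
  downsampling, bad-channel detection (kurtosis / probability / spectrum at
  5 SD, covariance at 3 SD) with spherical-spline interpolation, common
  average reference, epoching with baseline correction, artifact-based epoch
  rejection (±150 uV; kurtosis/probability 5 SD; 0-2 Hz ±50 dB; 20-40 Hz
  +25/-100 dB) and condition averaging.
* **Statistics** — pointwise one-sample t-maps of walking-minus-sitting
  difference ERPs; weighted-cluster-mass clustering
  (`sum((|t|-thresh)^w)`, `w = 1`) over an electrode adjacency graph;
  Monte-Carlo sign-flip permutation p-values (5,000 permutations, two-sided);
  Shapiro-gated paired t / Wilcoxon signed rank, independent t, mixed 2x2
  ANOVAs with eta-squared; and the two-stage step-up FDR
  (Benjamini-Krieger-Yekutieli) on the combined p-value set (scalar tests
  plus the minimum cluster p per EEG comparison).
* **Synthetic cohorts** — a first-class generator emulates all three
  streams (240-trial blocks, 13% NoGo, 1,017-ms SOA; quasi-periodic 3D heel
  traces with controllable stride jitter; ERP epochs built from N2/P3/ERN
  and premovement-positivity templates plus spatially correlated 1/f noise,
  with injectable walking-related amplitude effects), so the whole pipeline
  is testable without external recordings.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic cohort (26 participants; results land in `results/`):

```sh
Rscript analysis/01_simulate.R     # generate the cohort (cached in scratch/)
Rscript analysis/02_behavior.R    # d', RT, improver classification
Rscript analysis/03_gait.R        # mean DTW per participant x load
Rscript analysis/04_erp_cluster.R # ERP averaging + cluster permutation tests
Rscript analysis/05_stats_fdr.R   # scalar tests + combined two-stage FDR
```

With the default seed these print, among other things:

```
d' sitting 1.87 +/- 0.37, walking 2.36 +/- 0.32
classification threshold (1.96 x cohort SD): 0.942
mean DTW distance ST: 2.50 +/- 0.85 m  DT: 2.12 +/- 0.71 m
epoch rejection: 1.1% of epochs on average
electrode graph: mean degree 5.8 at max_dist 0.45
cohort / correct_rejection: min cluster p = 8e-04
...
FDR set size: 18 | critical p: 0.0024
```

Read: walking improves `d'` in this synthetic world (the improver-like
group carries the gain), dual-task walking is *less* variable than
single-task walking (mean DTW 2.12 vs 2.50 m), and the injected
walking-related ERP amplitude reductions surface as significant
spatiotemporal clusters at the cohort level, surviving the combined
two-stage FDR at `q = 0.05`. The same numbers come out of a single call:

```r
library(mobidt)
cohort <- simulate_cohort(seed = 1)          # default 26-participant world
report <- run_pipeline(cohort, seed = 1)     # full chain + FDR audit
report$fdr_set                               # combined p-value set + mask
```

## Acceptance script

`scripts/acceptance.R` regenerates the default synthetic cohort from the
given seed, runs the complete pipeline (scoring, classification, gait DTW,
epoch rejection, ERP averaging, six cluster permutation analyses, scalar
tests, combined FDR) and writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/`, `src/` — the package (all computation lives here; Rcpp kernels for
  DTW, cluster labeling and filtering)
* `analysis/` — numbered narrative drivers over the package
* `tests/testthat/` — unit, property and acceptance suites (exhaustive DTW
  oracle, permutation family-wise-error calibration, effect-recovery and
  classification-calibration simulations, frozen two-stage-FDR references)
* `vignettes/methods.Rmd` — the model, parameter and design-choice account
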