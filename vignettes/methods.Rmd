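---
title: "Dual-task MoBI analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-task MoBI analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mobidt` implements the analysis chain of a mobile brain/body imaging (MoBI)
dual-task experiment in which participants perform a visual Go/NoGo response
inhibition task while sitting or walking on a treadmill. Three measurement
streams are analyzed jointly:

* **behavior** — button presses to Go stimuli, withheld presses to NoGo
  stimuli (a NoGo being an immediate image repeat);
* **gait kinematics** — 3D heel-marker trajectories at 360 samples/s;
* **EEG** — 64-channel scalp recordings reduced to condition-averaged
  event-related potentials (ERPs).

No public recordings accompany this design, so the package ships a
synthetic-cohort generator that emulates all three streams with controllable
group structure. Every downstream stage is exercised end to end on that
generator; the generator is first-class, tested code.

# Behavioral model

Each block holds 240 trials at a fixed 1,017-ms stimulus-onset asynchrony,
13% of which (31 trials) are NoGo. Responses earlier than 183 ms
post-stimulus are treated as delayed responses to the previous trial and
discarded; the boundary is exclusive (a response is accepted only strictly
after 183 ms), mirroring the task's "only after" acceptance rule. Boundary-
valued synthetic response times are avoided in tests so this choice is not
load-bearing.

Sensitivity is the signal-detection index

$$d' = \Phi^{-1}(\mathrm{HR}) - \Phi^{-1}(\mathrm{FAR}),$$

with hit and false-alarm rates pooled over all seven blocks of a motor
condition. The orientation (hit-rate quantile first) follows the convention
that a larger $d'$ means better discrimination. Perfect rates are
edge-corrected with the log-linear rule (add 0.5 successes and 1 trial);
the underlying study does not state its edge handling, so this is our
documented choice (it is unbiased and standard, and it only engages at
rate 0 or 1).

Trials preceding correct rejections and false alarms must themselves be hits
for those trials to enter the EEG analyses (`preceded_by_hit`), ensuring an
inhibitory context.

# Gait variability model

A gait cycle is the interval between two consecutive heel strikes of the
same foot. Heel strikes are local maxima of the fore-aft (Z) heel position
with topographic prominence above 0.1 m, computed on the raw series. Cycles
are resampled to exactly 100 points (linear interpolation per coordinate) so
that dynamic time warping (DTW) costs are comparable across cycles; DTW uses
the 3D Euclidean local cost, the symmetric match/insert/delete step pattern,
no warping window and no path normalization, returning the unnormalized
minimal cumulative cost in meters. Stride-to-stride variability is the mean
DTW distance over all consecutive-cycle comparisons, pooled across feet.

Outlier cycles are removed before comparison: each cycle's statistic is the
sample kurtosis per coordinate, reduced by the **maximum across the three
coordinates**, and cycles beyond 5 SD from the cohort-condition mean are
dropped. The source design mentions only "a kurtosis" per cycle; max-over-
axes is the most conservative detector and is our documented choice, as is
pooling the outlier statistics across feet within a participant-condition.
Removed cycles create a new adjacency between their neighbors, i.e.
"consecutive" refers to the kept sequence.

# EEG preprocessing

The filtering front end is a zero-phase Chebyshev Type II lowpass (passband
ripple 1 dB, stopband attenuation 65 dB per pass, doubled by the
forward-backward application). No highpass is applied anywhere in the ERP
path, to avoid distorting slow components. Because no signal-processing
package ships with the supported stack, the design chain (analog prototype,
lowpass transform, bilinear transform, second-order sections, steady-state
initial conditions, odd-reflection padding) is implemented in the package
and was verified during development against an independent reference
implementation to 1e-14 in magnitude response. Downsampling (2,048 to 512
Hz) lowpasses with the stopband at the target Nyquist (256 Hz) and passband
at 0.8x that — the anti-aliasing corner is not specified by the source
design, so this is a documented choice.

Bad channels are flagged by four across-channel statistics: sample kurtosis
(5 SD), joint negative log-probability of the channel's values under the
pooled empirical amplitude distribution (5 SD), band-averaged log-spectral
deviation (5 SD), and mean absolute covariance with the other channels
(3 SD). The "probability" statistic names a method rather than a formula in
the source; our pooled-histogram implementation is EEGLAB-style and
documented as a choice. Flagged channels are rebuilt by order-4 spherical-
spline interpolation (Perrin-type kernel, 20 Legendre terms, ridge
regularization 1e-5), then all channels are re-referenced to the common
average.

Stimulus-locked correct-rejection epochs span [-200, 800] ms (baseline
[-100, 0] ms); response-locked false-alarm epochs span [-500, 500] ms
(baseline [-400, -300] ms). Epoch rejection applies, in a fixed order with
statistics computed once on the incoming set: absolute voltage (±150 uV),
per-channel kurtosis and joint probability (5 SD across epochs), 0-2 Hz
band log-power deviation (±50 dB; eye movements) and 20-40 Hz deviation
(+25 / -100 dB; muscle). The evaluation order is unstated in the source;
fixing it (voltage, kurtosis, probability, low band, high band) makes runs
deterministic. Independent-component decomposition and automatic component
labeling are out of scope (they require trained classifier weights); the
preprocessing chain exposes that stage as an identity pass-through.

# Cluster-based permutation statistics

For each participant the walking-minus-sitting difference ERP is formed per
electrode; one-sample t statistics against zero are computed at every
(electrode, timepoint) cell. Supra-threshold cells (two-tailed parametric t
quantile at alpha = 0.05, df = n-1) are clustered: same electrode at
consecutive timepoints, or neighboring electrodes at the same timepoint;
clusters are sign-homogeneous. The cluster statistic is the weighted cluster
mass $\sum (|t_i| - t_{\mathrm{thresh}})^{w}$ with $w = 1$ by default (the
exponent is configurable because the weighted-cluster-mass family admits
one).

The null distribution is built from 5,000 random sign flips of the
participant difference waveforms — the paired-design exchangeability
argument makes this equivalent to condition-label shuffling at far lower
cost. Per permutation the maximum cluster mass per sign is recorded; each
observed cluster's p-value is $(1 + \#\{\mathrm{perm max} \ge
\mathrm{observed}\}) / (1 + n_{\mathrm{perm}})$ against the same-sign null,
doubled for two-sidedness and capped at 1. The +1 terms avoid zero
p-values.

The electrode neighborhood is a chord-distance threshold on the spherical
montage (default 0.45, mean degree about 6 on the shipped 64-channel
layout). The source design relies on a toolbox default for adjacency and
does not print the weighted-mass exponent; both are configuration knobs
recorded in the output metadata, and cluster geometry may therefore differ
in detail from any particular reference figure. Family-wise error of the
whole procedure is verified by simulation in the test suite: under an
exchangeable null the any-significant-cluster rate over 200 simulated
cohorts must lie in the binomial band around 0.05.

# Scalar statistics and multiplicity

Paired comparisons are gated by a Shapiro-Wilk test at 0.05: paired t when
normality is not rejected, Wilcoxon signed rank otherwise. The Wilcoxon path
reports the tie- and continuity-corrected normal-approximation z (exact
enumeration backs it in tests for small n). Effect sizes follow the
reporting conventions: Cohen's $d = t/\sqrt{n}$ for paired t, Cohen's
$r = |z|/\sqrt{2n}$ for Wilcoxon (observations across both conditions), and
classical eta-squared (effect SS over total SS) for the mixed 2x2 ANOVAs,
which test the between factor against subject-within-group error and the
within factor and interaction against the subject-by-condition error.

A participant is an improver (IMP) when the walking-minus-sitting $d'$
difference exceeds $z_{0.975}\,\hat\sigma$, where $\hat\sigma$ is the
(n-1) sample SD of the whole cohort's differences, the candidate included
("the entire cohort"). The threshold construction is two-sided but only
positive exceedance maps to IMP: significant decliners are grouped with the
non-improvers. Note that under this literal criterion, labeling roughly half
of a cohort IMP is only possible when the difference distribution is
strongly skewed; the test suite verifies instead the criterion's calibration
(about 2.5% upper-tail labels under a pure null cohort).

Multiplicity is controlled by the two-stage step-up false discovery rate:
stage 1 runs Benjamini-Hochberg at $q' = q/(1+q)$ to estimate the number of
true nulls, stage 2 reruns the step-up at the sharpened level. The combined
set takes one p-value per paired/independent test, three per ANOVA, and the
minimum cluster p-value per EEG comparison (a comparison with no clusters
contributes nothing). The exact accounting that produced the reference
design's 16-entry set is partially ambiguous between main and post-hoc
tests; the pipeline's assembly (three cohort-level scalars, one independent
t, two ANOVAs times three, two post-hoc paired t, and up to six EEG
comparisons) is one consistent reading and is fully recorded in the audit
table.

# The synthetic world

The generator's defaults are the stated experimental conditions: 26
participants (14 improver-like, 12 non-improver-like), 7 blocks x 240
trials x 2 motor conditions, 13% NoGo, 1,017-ms asynchrony. Where the
design prints group summaries, those are the generator's group parameters:
mean Go RTs 360/372 ms (improver sitting/walking) and 407/411 ms
(non-improver), with across-participant SDs 54/41 and 64/47 ms. Hit and
false-alarm rates (0.95/0.35 sitting for improvers, improving to 0.97/0.18
walking; 0.95/0.30 in both conditions for non-improvers) place sitting
$d'$ near 2.0-2.2 and give improvers a walking gain of about 0.8 —
magnitudes consistent with the printed cohort summaries.

Values the design does not print were chosen once, for realism, and are not
revisited:

* **Response-time model**: truncated normal with a 100-ms floor;
  trial-to-trial scatter 80 ms. Participant-level random effects (a speed
  factor correlated 0.85 across motor conditions; hit/false-alarm logit
  offsets shared across conditions so they cancel in the walking-minus-
  sitting difference; a lognormal gait-variability factor with log-SD 0.25)
  reproduce the printed across-participant dispersions.
* **Gait waveform**: a smooth template heel path (near-sinusoidal 0.7-m
  fore-aft excursion, vertical stance bumps plus swing-phase lift, 2-cm
  lateral sway) at a 1.1-s stride period quantized to the 360-Hz sample
  grid, perturbed per cycle by a smooth low-order harmonic field whose
  amplitude is the jitter knob (meters). Jitter defaults (improvers
  0.012/0.010 m ST/DT, non-improvers 0.014/0.012 m) put mean DTW in the
  printed 2.1-2.8 m range with the printed orderings (DT < ST, improvers <
  non-improvers). Period quantization makes the jitter-0 world exactly
  cycle-periodic, so mean DTW 0 is an exact invariant there.
* **ERP templates**: Gaussian time courses times Gaussian scalp weightings —
  a frontocentral N2 (-3 uV at 275 ms) and broad centroparietal P3 (+6 uV
  at 450 ms) for correct rejections; a central premovement positivity
  (+3 uV at -130 ms) and frontocentral error-related negativity (-4 uV at
  +40 ms) for response-locked false alarms. Walking effects are injected
  only in the improver-like group: +2.5 uV frontocentral in the
  conflict-monitoring window and across the premovement/error windows
  (reduced negativities), -2.5 uV centroparietal in the control-
  implementation window (reduced positivity) — signs matching the reported
  walking-related amplitude reductions.
* **EEG noise**: 1/f-shaped (exponent 1) in time, spatially mixed with
  exp(-d/0.5) weights on the unit-sphere montage, marginal SD 8 uV per
  sample; 60 epochs per condition. These give within-participant difference
  waveforms an SD near 1.5 uV, a regime where improver-group effects are
  reliably detected and null groups stay null — mirroring the qualitative
  reference result.

What the generator does **not** emulate: volume-conducted artifacts with
realistic spatial topographies (eye/muscle plants in tests are stylized),
gait-locked EEG artifacts, non-stationary drift across blocks, image-
content effects, or continuous raw EEG with embedded events (epochs are
generated directly). A green end-to-end test therefore establishes that the
analysis machinery recovers the structure this world contains — not that it
would be robust to every artifact class of real mobile EEG.

# Numerical choices and degenerate inputs

* Zero-variance cells in t-maps are guarded to a large finite sentinel
  (sign of the mean); all-zero difference data yields p = 1 everywhere.
* Zero across-channel or across-epoch SDs in artifact statistics flag
  nothing (identical-input guard), so rejection is idempotent on fixtures
  whose clean members are identical.
* DTW on equal trajectories is exactly 0; the implementation is verified
  against an exhaustive warping-path enumeration for short trajectories.
* The classification null uses the n-1 sample SD; a zero-SD cohort is a
  degenerate-input error rather than a silent all-nIMP answer.
* Permutation seeds: every stochastic stage takes an explicit seed, and a
  fixed seed reproduces the cohort and every downstream number bit-for-bit.

# Known limitations

* The raw-recording front end (BDF ingestion, continuous-data bad-channel
  flows) is exercised on synthetic continuous arrays, not on vendor files:
  no BDF reader exists in the supported dependency stack, and epochs are
  generated directly by design.
* Independent-component artifact removal is a pass-through hook.
* The improver classification reproduces the stated criterion literally;
  as noted above, its behavior on strongly bimodal cohorts differs from
  what a reader might infer from the reference split sizes.
* Between-group direct permutation contrasts (improvers versus
  non-improvers on the difference waveforms) are intentionally out of
  scope; each group is tested separately.
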