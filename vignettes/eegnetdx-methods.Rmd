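---
title: "EEG network diagnostics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG network diagnostics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegnetdx)
```

## The problem

Interictal EEG in children with partial epilepsy is often normal to visual
inspection, so a diagnosis based on epileptiform discharges alone misses a
substantial fraction of patients. The hypothesis behind this package is that
the *functional network* of the resting brain — the pattern of statistical
interdependence among EEG channels — carries diagnostic information even
when no single spectral or network quantity separates groups on its own.
The pipeline therefore (1) estimates a weighted functional network per
subject from artifact-free resting epochs, (2) summarizes it into a small
feature vector of network characteristics, and (3) feeds those features to
a multivariable classifier whose performance is estimated with an internal
validation that guards against optimism.

## Recording model and preprocessing

The unit of data is an `eeg_recording`: a set of equal-length epochs
(channels x samples) at a common sampling rate. The reference geometry used
throughout defaults and tests is 17 scalp channels, 512 Hz sampling and
four 8-second epochs per subject — a routine clinical resting-state
protocol after exclusion of frontopolar/auricular channels dominated by eye
movement.

All analyses run on band-filtered data. `bandpass()` applies a 4th-order
Butterworth filter forward and backward (`signal::filtfilt`), so the net
response is zero-phase: phase distortion would directly bias the
delay-embedding on which the connectivity index is built. The canonical
bands are broadband 0.5–45 Hz and delta (0.5–4), theta (4–8), alpha
(8–12), beta (12–30) and gamma (30–45 Hz). We verified numerically that
the transfer-function form stays stable at the awkward 0.5 Hz lower edge
at fs = 512; the band edge sits at 0.002 of Nyquist, where higher-order
designs can misbehave.

`compute_psd()` uses Welch averaging with 2-s Hann windows and 50%
overlap. The window length is a deliberate choice: 2 s gives 0.5 Hz
resolution, exactly resolving the lowest band edge. Power is reported both
absolute (units²/Hz) and relative (normalized per channel over the
0.5–45 Hz grid, summing to 1). Spectra are averaged over a subject's
epochs first, then over subjects.

## Synchronization likelihood

Connectivity is quantified by the synchronization likelihood (SL), a
[0, 1] measure of generalized synchronization. Each channel is
delay-embedded (`embed_delay()`); for each reference time *i* a critical
distance ε_i is calibrated such that the fraction of embedded neighbours
*j* within ε_i — among eligible times with w1 < |i − j| ≤ w2 — equals a
reference probability p_ref (`critical_distance()`). The Theiler window w1
removes autocorrelated neighbours, the outer window w2 bounds the search
horizon. SL between channels x and y is then the conditional probability
that y is recurrent at a time pair where x is recurrent, averaged over
reference times and symmetrized by averaging the two directions
(`sl_matrix()`). Two properties make SL self-calibrating:

* independent channels give SL ≈ p_ref (the package verifies
  0.05 ± 0.02 at 4096 samples), and
* identical channels give SL = 1.

Parameter defaults follow the frequency-adaptive prescription tied to the
analysis band: lag = round(fs/(3 f_hi)), m = round(3 f_hi/f_lo) + 1 capped
at 16, w1 = 2·lag·(m − 1), w2 = w1 + floor(10/p_ref), p_ref = 0.05. For
broadband data at 512 Hz this gives m = 16, lag = 4, w1 = 120, w2 = 320.
Every value is overridable through `sl_params()`. Numerical details: the
neighbour count at each reference is k = max(1, round(p_ref·n_eligible))
with half-values rounded away from zero; ties at the critical distance are
included; Euclidean distance in embedding space; zero-variance channels
saturate the calibration and are assigned SL 0 against every other channel
with a warning rather than propagating 0/0. The SL core is implemented in
C++ (exact, not approximate: a testthat oracle reproduces it in plain R
double loops to 1e-12).

Per-epoch SL matrices are averaged element-wise into one symmetric,
zero-diagonal matrix per subject (`subject_connectivity()`), which is the
subject's functional network. No thresholding is applied; the graph stays
complete and weighted.

## Network characteristics

`feature_vector()` reduces a subject's network to 18 scalars: min/mean/max
of node strength, weighted shortest path length, closeness, eigenvector
centrality and weighted clustering; mean/max of betweenness; and the
power-law scaling index of the strength distribution.

Design choices where the field offers alternatives:

* **Distance convention.** Path metrics use edge length 1/w — strong
  synchronization is short functional distance. 1/w (rather than −log w
  or 1 − w) is the convention of the software lineage these
  characteristics come from.
* **Betweenness.** Unnormalized transit counts over *ordered*
  source–target pairs, endpoints excluded, shortest-path multiplicity
  counted exactly. Floating-point ties in path length are resolved with a
  1e-12 relative tolerance; distances come from Floyd–Warshall, path
  counts from a Brandes-style accumulation. On a 17-node dense graph
  exactness is cheap, and the tie tolerance is not available in the usual
  library routines, which is why these two metrics are computed in-package
  (igraph serves as an independent cross-check in the test suite).
* **Eigenvector centrality** is the Perron vector of W, computed by power
  iteration, oriented nonnegative, unit Euclidean norm, with the eigen
  equation residual checked to 1e-10.
* **Clustering** uses the Onnela geometric-mean triangle intensity on
  max-normalized weights; a Zhang-style normalization is available via
  `method = "zhang"`.
* **Power-law index.** Continuous MLE
  α = 1 + n/Σ log(d_i/d_min). With only 17 node strengths a lower-cutoff
  scan is statistically fragile, so d_min defaults to the minimum strength
  (all nodes in the tail); `method = "ks"` enables a Kolmogorov–Smirnov
  cutoff scan for larger graphs. Equal strengths leave α undefined and
  raise a distinct error. Fitting a tail exponent to 17 observations is
  inherently noisy; the feature is retained because the modelling target
  is discrimination, not accurate exponent recovery.

## Classifier and internal validation

`fit_forest()` wraps a random forest (500 trees; 5 of the 18 features
tried per split, the value reported to maximize accuracy in this setting)
whose score is the fraction of trees voting "case". Same-data evaluation
of such a model is optimistic, so `bootstrap_validate()` reports only
internally validated estimates: for each of B replicates (default 1000),
subjects are resampled with replacement *within* group, the forest is
refit, and only out-of-bag subjects are scored. Replicate ROC curves, AUC
(trapezoidal, equal to the Mann–Whitney concordance; verified exactly
against pair counting), and operating-point metrics at the Youden-J
threshold are averaged across replicates; 2.5th/97.5th percentiles give
95% confidence intervals; the averaged ROC is built by vertical averaging
on a 101-point false-positive-rate grid. Replicates whose out-of-bag set
misses a group are skipped (error if more than 20% are). A Harrell-style
optimism-correction mode is available (`mode = "optimism"`).

Two open choices deserve a note. The operating threshold is the Youden-J
maximizer because no clinical operating rule is implied by the data; and
`mtry` stays fixed by configuration rather than tuned, because tuning on
the same data that is bootstrapped for validation would leak information.

`per_feature_ttest()` (pooled-variance Student t, unadjusted, Holm
optional) and `feature_correlation()` mirror the expected univariate
picture: on null cohorts ~5% of features reach p < 0.05 while the
multivariable model stays at chance.

## The synthetic cohort generator

No clinical recordings ship with the package, so `generate_cohort()`
provides a fully synthetic two-group cohort with a controllable coupling
difference. Each channel is a stochastic alpha-band oscillator — an AR(2)
process with spectral peak at 10 Hz and pole radius 0.97, matching the
eyes-closed resting condition — scaled to unit variance, plus white sensor
noise (noise_sd, default 0.5). Inter-channel dependence comes from shared
latent drivers mixed into channels by amplitude:

    channel = sqrt(1 − b² − w²)·private + b·global_driver + w·focal_driver + noise_sd·ε

with b = base_coupling into every channel and w = effect_size into a fixed
contiguous block of roughly a third of the channels (`focal_channels()`),
in the case group only. The invariant base_coupling + effect_size < 1
keeps the oscillatory part at unit variance. Latent-driver mixing was
chosen over phase-coupled oscillators because it is the simplest mechanism
that produces generalized synchronization detectable by SL with a single
scalar knob, and because SL on the focal edges is then provably
nondecreasing in effect_size. Default base_coupling = 0.3 gives every
pair a weak common signal (realistic volume-conduction-free background
synchrony); effect_size = 0.5 is a planted difference strong enough for a
35 + 35 cohort to be separable after SL estimation noise.

Determinism: each subject draws from a substream derived from the master
seed and a fixed per-group offset, so cohorts are bit-reproducible and
individual subjects do not change when `n_per_group` changes.

What the generator does *not* emulate: volume conduction and electrode
geometry, 1/f broadband background, artifacts (the modelled epochs are
artifact-free by construction), and — deliberately — any claim about the
statistical structure of real epilepsy-vs-control differences, which the
clinical data do not constrain beyond "no single feature separates
groups". Passing tests on synthetic cohorts therefore demonstrate the
pipeline's internal correctness and calibration, not clinical accuracy.

## Problem sizes and numerical budgets

The package's own validation runs at three scales, chosen to keep the full
suite fast while still exercising the full reference geometry once:

* Oracle equivalence (SL, graph metrics, AUC) uses small inputs —
  epochs ≤ 512 samples, graphs with ≤ 7 nodes — where brute-force
  enumeration is exact and instant; agreement is required to 1e-9 (graphs)
  and 1e-12 (SL, AUC).
* Calibration studies (null-cohort AUC over 20 cohorts, planted-effect
  recovery over three effect sizes) use compact recordings (2 epochs of
  2–4 s at 256–512 Hz) with full-size groups (up to 35 + 35) and B of
  50–200; null calibration is insensitive to epoch length because
  exchangeability between groups holds at any recording size.
* One end-to-end run uses the full reference geometry: 70 subjects,
  17 channels, 4 x 8 s at 512 Hz, broadband SL, B = 100.

## Known limitations

* SL parameters for the clinical analyses this mirrors are conventions,
  not published facts; results can shift with m, lag and p_ref, which is
  why they are explicit, printed, and overridable.
* The 17-point power-law fit is fragile by construction (see above).
* Percentile bootstrap CIs are used throughout; DeLong-style analytic AUC
  CIs are not implemented (pROC can provide them externally if needed).
* The bootstrap does not preserve matched case–control pairs, since no
  pairing rule survives resampling with replacement in a stratified
  design.
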