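---
title: "Higuchi fractal dimension analysis of multichannel EEG: models, tuning and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higuchi fractal dimension analysis of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfdeeg)
```

## The problem

Cortical dynamics are nonlinear, and during long, naturalistic cognitive
tasks (here: multi-slide mathematics demonstrations lasting tens of
seconds) many overlapping processes modulate the EEG at once. Linear
descriptors such as band power summarize oscillatory content but miss
complexity differences between groups of subjects — for example between
mathematics experts and novices solving the same problems. The Higuchi
fractal dimension (HFD) is a time-domain complexity measure that is cheap,
robust on short and nonstationary segments, and bounded between 1 (smooth,
predictable signal) and 2 (uncorrelated noise). This package implements a
complete HFD analysis chain for a two-group, high-density EEG study — from
signal-level estimation through channel statistics to classification — and,
because the corresponding human data cannot be redistributed, a calibrated
synthetic cohort generator that reproduces the statistical structure the
analysis assumes, so every stage is testable end to end.

## The estimator

For a series $x(1), \dots, x(N)$, subsampling interval $k$ and phase
$m \in \{1, \dots, k\}$, the normalized curve length is

$$L_m(k) = \frac{N-1}{M k}\cdot\frac{1}{k} \sum_{i=1}^{M}
  \left| x(m+ik) - x(m+(i-1)k) \right|, \qquad
  M = \left\lfloor \frac{N-m}{k} \right\rfloor ,$$

and $L(k)$ is the mean of $L_m(k)$ over the $k$ phases. For a self-affine
signal $L(k) \propto k^{-D}$, so the HFD is estimated as the ordinary
least-squares slope of $\log L(k)$ against $\log(1/k)$ over
$k = 1, \dots, k_{\max}$ (`higuchi_fd()`). Implementation choices:

* every integer $k$ from 1 to $k_{\max}$ enters the fit (no logarithmic
  subsampling of $k$);
* natural logarithms (the slope is base-invariant; fixed for
  reproducibility);
* a constant (or constant-after-subsampling) window is an error, not a
  sentinel value — callers that window a signal may catch and skip;
* the optimized C++ path is validated against `higuchi_fd_naive()`, a
  plain-R triple loop built from the same `curve_length_m()` /
  `curve_length()` primitives, to $10^{-10}$ on random signals.

Anchor values: a linear ramp gives $L(k) \propto 1/k$ exactly up to floor
effects, hence slope 1.000; Gaussian white noise gives 2.0; both are
asserted in the test suite. The estimator is exactly invariant under affine
transforms $a x + b$ of the signal.

`windowed_hfd()` computes one HFD per complete non-overlapping window
(trailing remainder discarded), which is the recommended mode for
nonstationary signals and is used by the presentation-specific
classification with windows of 5, 8 or 11 s.

## Choosing $k_{\max}$

$k_{\max}$ is the method's key hyperparameter: the fitted slope grows with
$k_{\max}$ and then plateaus, and too small a value leaves channels
indistinguishable. `sweep_kmax()` computes, over a candidate grid
(default $\{2, 5, 20, 100, 150, 200, 400\}$),

* the grand mean HFD over all recordings and channels, and
* the grand mean of the per-recording *channel spread* — the maximum minus
  the minimum HFD across channels, reading the minimum as the baseline
  dimension and the maximum as the complexity of the most responsive
  channels.

`select_kmax()` picks the candidate that maximizes the mean spread;
among candidates whose spread is within `plateau_tol` (relative, default
0.02) of that maximum it prefers the smallest one whose mean HFD is within
`plateau_tol` of the final candidate's (i.e. has reached the plateau), and
ties break toward the smaller candidate. The dual criterion in the
originating methodology is verbal ("largest difference", "plateauing");
the single relative tolerance is this package's formalization of it.
Curve lengths are computed once per channel up to the largest feasible
candidate and re-fit on prefixes, so the sweep costs about one extraction
at the largest candidate. Two further choices were genuinely open and are
fixed here: the spread is computed per recording and then averaged (not
max-of-means), and candidates a recording is too short for
($2 k_{\max} > N$) are skipped for that recording with a warning rather
than failing the sweep.

## Channel-level group statistics

The per-channel contrast is the double mean
$\Delta \mathrm{HFD}_{ch} = \overline{\overline{\mathrm{HFD}}}_{expert} -
\overline{\overline{\mathrm{HFD}}}_{novice}$: HFD averaged over
presentations within a subject, then over subjects within a group
(`delta_hfd()`; antisymmetric in the group order by construction).
`channel_tests()` runs per-channel two-sample t-tests **on subject-level
means**: with 16 presentations per subject, treating subject-presentation
pairs as units would pseudo-replicate; subjects as units is the
conservative choice. Defaults, each switchable:

* Welch's unequal-variance test (the pooled-variance test is a flag);
* one-sided in the direction *novice > expert*, reflecting the expected
  higher frontal complexity in novices; both directions and two-sided are
  supported since the contrast itself is signed;
* significance at uncorrected $p < 0.05$, with a Benjamini–Hochberg
  adjusted column always emitted alongside for the reader;
* `top_channels()` ranks by absolute difference (signed optional), ties
  broken by channel label order.

The same machinery applied to the eyes-open resting recordings is the
negative control: the generator places no group effect at rest, and the
tests must find none beyond the chance rate. `style_contrast()` compares
algebraic against geometric presentations within one group with a paired
test across subjects; the generator draws both styles identically, so this
is a second null control. `export_topography()` emits (channel, delta, p)
in montage order for any topographic plotting tool; rendering scalp maps
is out of scope.

## Classification under three split schemes

Samples are subject-presentation pairs (44 subjects × 16 presentations =
704 at full scale), each carrying one HFD per retained channel — 124
features whole-signal, or (T/N) × channels in windowed mode. Three
cross-validation schemes differ only in what a fold may separate:

1. **subject-presentation** — rows shuffled freely; samples of one subject
   can sit on both sides of a fold, so the classifier may exploit subject
   identity;
2. **subject-specific** — subjects partitioned; all rows of a subject
   follow the subject, eliminating identity leakage;
3. **presentation-specific** — each presentation is its own task over its
   44 rows, split at subject level; only here is windowed mode meaningful,
   because all rows of one presentation share a duration by design.

The classifier grid is fixed: k-nearest neighbours (3, 5, 7, 9, 11
neighbours), linear-kernel SVM (C = 0.025, 0.5, 0.75), decision tree
(depth 3, 5, 7) and AdaBoost over depth-1 stumps (25, 50, 100 rounds).
kNN, SVM and trees call `class`, `e1071` and `rpart`; the discrete
two-class AdaBoost reweighting loop is implemented in the package, as no
boosting package is among the dependencies. Protocol choices:

* hyperparameters are selected by mean ten-fold validation accuracy under
  scheme 1, averaged over the three CV seeds, then **frozen** for schemes
  2 and 3 — the simplest faithful reading of tune-once-then-evaluate;
* the three seeds are fixed to $\{0, 1, 2\}$ as the concrete reading of
  "averaged over 3 random seeds"; per-seed accuracies are retained in the
  report;
* features are standardized with training-fold statistics only (distance-
  and margin-based classifiers need it; toggleable, and no information
  crosses the fold boundary);
* the metric is plain validation accuracy — classes are balanced at the
  generator's defaults, so no AUROC is reported;
* per-pair samples (704 × 124) are used for scheme 2 as well; the
  alternative concatenated-per-subject reading is intentionally not the
  default since it changes the sample count and feature dimension.

`compare_channel_sets()` reruns the identical pipeline on the full montage
and on the 32-channel standard 10/20 subset. The default synthetic
configuration places the effect channels *outside* the standard subset, so
the full montage must win — the mechanism behind the empirical observation
that channel reduction costs accuracy when the most discriminative sites
are high-density-only.

## The synthetic cohort

Real high-density EEG of this study design is not redistributable, so the
generator produces a cohort with the statistical structure the analysis
assumes — and nothing more. Each brain channel is power-law Gaussian noise
with spectral density $S(f) \propto f^{-\beta}$, $\beta = 5 - 2D$
(equivalently the fractional-Brownian-motion relation $D = 2 - H$),
synthesized by filtering white noise in the frequency domain in
$O(n \log n)$; this was chosen over exact Davies–Harte fBm synthesis for
simplicity and speed, with a Monte-Carlo calibration property (estimated
HFD regressed on target $D$ over $\{1.2, 1.4, 1.6, 1.8\}$: slope within
$[0.7, 1.3]$, rank order preserved) as the guard. Structure:

* **groups and design**: 22 experts + 22 novices, 8 matched
  algebraic/geometric presentation pairs (durations drawn once, uniform on
  13–68 s, identical across subjects and within a pair), one eyes-open
  rest recording each;
* **montage**: 129 channels = 124 EEG (the 32 standard 10/20 labels plus
  92 filler sites E1..E92) + 5 auxiliaries (VEOGL, HEOGL, HEOGR, VEOGU,
  HEART) carrying unrelated white noise; all labels configurable;
* **effect**: during task only, the configured group (default novices)
  receives an FD offset (default +0.15) on the effect channels (default
  E1..E4, deliberately outside the 10/20 subset); rest recordings carry no
  group effect by construction;
* **subject variability**: one additive FD offset per subject
  (sd 0.05), shared across all channels and recordings of that subject —
  the simplest structure that makes subject-specific splits measurably
  harder than pooled splits;
* **noise**: white measurement noise at relative amplitude 0.05, folded
  into the spectral amplitude in quadrature (exactly equal in law to an
  independent additive white signal, and cheaper);
* **band limit**: brain-channel synthesis is cut off at 40 Hz, standing in
  for band-limited acquisition and preprocessing; no filter stage exists.
  A consequence worth knowing: below the cut-off scale the signal is
  smooth, so the mean HFD versus $k_{\max}$ curve rises and then
  plateaus — the qualitative shape the tuning procedure expects — and
  whole-signal estimates at moderate $k_{\max}$ sit slightly below the
  configured targets while preserving their order;
* **determinism**: every recording's seed is a deterministic hash of the
  master seed and the recording's identity, so cohorts are reproducible
  byte-for-byte and single recordings can be regenerated lazily without
  storing anything.

FD targets are clamped to $(1.01, 1.99)$ since the spectral exponent
degenerates at the endpoints. The sampling rate defaults to 256 Hz
(desk scale); the acquisition-grade 2048 Hz is a configuration value.
Durations and counts are the study's; effect size, subject variability and
noise level are this package's choices of a realistic regime, since the
source analyses report no variance components — no claim is made that the
synthetic effect magnitudes match any published absolute
$\Delta\mathrm{HFD}$.

What the generator does **not** emulate: event-related potentials, eye
blinks or cardiac bleed-through into brain channels, line noise, electrode
drift, volume-conduction correlations between neighbouring channels,
within-recording nonstationarity, and deviations from an exact power law.
Passing tests therefore show that the pipeline is correct and calibrated
under its stated assumptions — not that real EEG satisfies those
assumptions.

## On-disk formats and interfaces

Recordings serialize as one columnar CSV per recording (header row of
channel labels, full double precision) with a JSON metadata sidecar, plus
a cohort-level `manifest.json`; reading validates geometry against the
sidecar and reports truncation by field name. EDF export is not provided —
no EDF writer exists among the package's dependencies and the CSV/JSON
pair already round-trips losslessly. There is no shell command-line tool:
the exported functions, `run_pipeline()`, and the numbered scripts under
`analysis/` *are* the interface, which suits an analysis package better
than a binary would. `run_pipeline()` additionally writes a run manifest
with MD5 checksums of every emitted table, making the
pure-function-of-(config, seeds) property checkable.

## Problem sizes used by the tests

The test suite and `scripts/acceptance.R` run the structural checks at the
full default scale (44 subjects, 16 presentations, 256 Hz: 704 samples ×
124 features) and all Monte-Carlo properties on reduced cohorts (4–22
subjects per group, 1–2 presentation pairs, 16–24 EEG channels, 5–16 s
recordings), with estimator-validity checks at $N = 8192$ samples averaged
over 20 seeds and $k_{\max} = 100$. These sizes are the package's chosen
trade-off between Monte-Carlo resolution and a test run measured in
minutes; the full-scale generate-plus-extract pass takes several minutes
single-threaded.

## Known limitations

* The spread-based $k_{\max}$ selection inherits the conflation of
  "significant vs non-significant channels" with the max/min channel of
  the originating methodology; on short synthetic recordings the spread
  keeps growing with $k_{\max}$ (estimator variance at deep scales), so
  the selection can land on the largest candidate — stable, but driven by
  signal length rather than by an interior peak as on long recordings.
* Whole-signal HFD on nonstationary data is not representative; the
  windowed mode exists, but the synthetic signals are stationary, so the
  tests exercise the mechanics rather than the nonstationary use case.
* The AdaBoost implementation is the classic discrete two-class variant
  over stumps; it matches the grid's "number of estimators" semantics but
  is not a bit-exact replica of any particular library's boosting.
* p-values are reported uncorrected at $\alpha = 0.05$ by design (with a
  BH column alongside); with 124 channels, about six false positives are
  expected under the null, which the calibration tests confirm rather
  than hide.
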