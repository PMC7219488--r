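---
title: "Methods: simulating and quantifying rater reliability of MRCP peak-negativity labelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying rater reliability of MRCP peak-negativity labelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcprel)
```

## The problem

The movement-related cortical potential (MRCP) is a slow (~0.5 Hz) negative
EEG potential that begins roughly 1.5–2 s before a voluntary or imagined
movement and reaches its most negative point — the peak negativity (PN) —
around movement onset. PN timing is the anchor for closed-loop
neuromodulation protocols, and in practice it is obtained by a human expert
who (1) inspects cue-locked epochs one at a time, accepting or rejecting
each as a plausible MRCP, and (2) clicks the PN on the average of the
accepted epochs. `mrcprel` implements the full measurement chain needed to
study how reliable that process is — across repeat sessions of one rater and
across raters — and how epoch morphology drives agreement, using a synthetic
generator with known ground truth in place of unavailable human data.

The study design the package targets: three movement conditions (voluntary
dorsiflexion in healthy people, imagined dorsiflexion in healthy people,
voluntary dorsiflexion after stroke) × 10 datasets per condition × 50 epochs
per dataset; five raters evaluate every dataset at three sessions.

## Signal chain

Continuous recordings are band-pass filtered 0.05–5 Hz with a second-order
Butterworth filter applied forward and backward (zero phase; effective
magnitude |H(f)|²), spatially filtered with a large Laplacian centred on Cz
(centre minus the mean of Fz, Pz, C3, C4 — the only surrounding set
available on the sparse 10–20 montage; FP1 is excluded as an EOG-proxy
channel), and cut into 4.5 s epochs spanning 3 s before to 1.5 s after each
cue. At 500 Hz an epoch has 2250 samples with the cue at sample index 1500
(0-based). Cue times in seconds map to samples by round-half-away-from-zero;
epoch intervals are half-open.

Numerical choices in the filter: forward–backward IIR filtering is
initialised at the steady state for a constant input equal to the first
(padded) sample, so DC is nulled exactly, and the signal is extended by odd
reflection over about three time constants of the 0.05 Hz edge
(`ceiling(3 fs / (2π·0.05))` samples, capped at half the signal) before
filtering. Short reflective pads of a few samples are not enough here: the
low edge's transient decays with τ ≈ 4.5 s and would otherwise leak into
the epochs.

## Epoch metrics

* **Cosine similarity (CS)** of epoch *v* against the average *u* of all 50
  epochs in its dataset: `u·v / (‖u‖‖v‖)`. The all-epoch average (never an
  accepted subset) is the morphology reference. Zero-norm epochs are flagged
  invalid and excluded with a warning, never silently.
* **Average MRCP** per (rater, session): the mean of the epochs that rater
  accepted at that session.
* **PN label**: the most negative sample of an average within a search
  window, default −2000…+1500 ms relative to the cue (wide enough to cover
  the whole plausible MRCP time course); ties resolve to the earliest
  sample. Latency is reported in ms relative to the cue, the only time
  anchor the protocol defines.
* **Matched epochs**: intra-rater — accepted by the same rater at two named
  sessions; inter-rater — accepted by all raters at one session.
  Reject–reject pairs are *not* matched: matching is defined through
  acceptance only, so the match probability is the quantity the acceptance
  model drives.

## Reliability statistics

PN labels form complete datasets × raters (or sessions) matrices. A two-way,
one-observation-per-cell ANOVA decomposes them into between-dataset (MSR),
between-rater (MSC) and residual (MSE) mean squares, from which:

* **ICC(A,1)** — two-way random effects, absolute agreement, single
  measures: `(MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))`, with the
  F-based two-sided 95% confidence interval using Satterthwaite degrees of
  freedom for the mixed mean square. This is the agreement form: systematic
  rater offsets count as error.
* **SEM** = √MSE, the absolute error in milliseconds.
* **Bands**: excellent (> 0.8], good [0.6, 0.8], moderate [0.4, 0.6), poor
  (< 0.4). The boundary values 0.8 and 0.6 are closed into "good" — the
  verbal criteria overlap at the boundaries, so the closure is fixed here
  once and documented.

Negative point estimates are reported as computed (not clamped to zero),
flagged, and banded poor; clamping would hide exactly the degenerate
behaviour small-sample ICCs are known for. For strongly negative estimates
the Satterthwaite degrees of freedom can be undefined, in which case the CI
is NaN and flagged rather than fabricated. Incomplete rating matrices are an
error naming the missing cells — the design is complete by construction and
imputation is out of scope.

Simulation checks (in the test suite) show the estimator's bias at the
study size (n = 10, k = 5) is below 0.03 for true ICC in {0.5, 0.8, 0.95}
and the CI coverage is ~95%.

## Association models

* CS across conditions: linear mixed model `cs ~ condition + (1 | dataset)`
  by REML, followed by Tukey (studentized-range) pairwise contrasts of the
  condition means. With 30 datasets the contrasts carry 27 denominator df.
* Matched-epoch probability: logistic mixed model
  `matched ~ cs * condition + (1 | dataset)` fitted by adaptive
  Gauss–Hermite quadrature (25 nodes by default; 1 = Laplace). Per-condition
  CS trends are simple slopes (reference slope plus interaction) under
  treatment coding with healthy voluntary as reference. Interaction tests
  are likelihood-ratio tests; probability-vs-CS curves are inverse-logit
  transforms of the linear predictor with delta-method Wald bands computed
  on the logit scale, conditional on a random intercept of zero.

The random-effects structure is a single random intercept grouped by
dataset — the repeated unit across raters and sessions. Richer crossed
structures (rater, session) are deliberately out of scope; the grouping is
configurable. Experience enters as a continuous fixed effect in years when
requested.

## The synthetic generator

Each dataset draws a template: amplitude ~ Normal(per-condition mean, SD)
(clamped negative), PN latency ~ Normal(per-condition mean, between-dataset
SD) snapped to the sample grid. The waveform is a piecewise-cosine slow
negativity (flat baseline, cosine ramp from the ramp onset to the PN, cosine
recovery over 1 s) carrying (1 − `pn_peak_depth_frac`) of the amplitude,
plus a sharp cosine peak of half-width `pn_peak_width_ms` centred on the PN
carrying the rest. The sharp component reflects the distinct negative peak
of executed movements; imagined movement gets a wide, shallow peak
(600 ms, 15%) to model its less defined PN. Epochs scale the template by
Normal(1, 0.1), jitter its latency, and add background noise plus (with the
condition's artefact probability) a large, broad negative transient that
survives the 0.05–5 Hz band, so epoch rejection stays meaningful.

Background noise is an equal mixture of white and spectrally synthesised
1/f noise, band-limited 0.05–5 Hz by the package's own filter and scaled to
the condition's noise SD. The band limitation is deliberate: simulated
epochs stand for the *post-preprocessing* virtual channel, so their noise
must carry the same band limitation the pipeline imposes — broadband noise
would make single-sample PN localisation unrealistically unstable.

A note the extended parameter set deserves: the generative reliability
contract (expected ICC = σ²_dataset / (σ²_dataset + σ²_bias + σ²_noise))
needs a between-dataset variance component, so the condition parameters
include `pn_latency_between_sd_ms` (the "participant" spread of true PN
latency) alongside the epoch-level jitter.

### Calibration

Condition defaults are calibrated constants (see
`scripts/calibrate_similarity.R`): noise SDs 12.1 / 14.4 / 10.6 µV and
amplitude spreads 2 / 1.5 / 2 µV place the condition-wise grand mean CS at
≈ 0.39 (healthy voluntary), 0.27 (healthy imagined) and 0.41 (stroke
voluntary), with an across-seed SD of about 0.02 at the 10-dataset design
size, preserving the ordering HV ≈ SV > HI. Amplitude spreads were kept at
the low end of the plausible range specifically to keep the 10-dataset
grand mean stable across seeds.

### Simulated raters

Five raters with 1.5–8 years' experience (mean 4.7). Acceptance is
Bernoulli with log-odds linear in CS; the default intercepts and slopes are
condition-specific (slope 4.7 / 1.3 / 2.6, steep for clear voluntary MRCPs
and shallow for faint imagined ones) so that the implied matched-epoch
trends differ across conditions the way the evaluated protocol's do.
Decisions are conditionally independent across sessions given CS — rater
memory and training effects are deliberately not modelled. PN labels are
the automatic PN of the rater's own included-epoch average plus a fixed
rater bias (±~15 ms spread by default) and Gaussian noise (30 ms default).

Reproducibility: every stochastic operation runs on a private RNG
sub-stream keyed by a 31-bit hash of (master seed, entity path), so adding
raters or sessions never perturbs dataset noise, and any dataset can be
regenerated in isolation.

### What the generator does and does not emulate

It emulates: the morphology contrast between conditions (amplitude, PN
definition, latency, epoch-to-epoch similarity), artefact-contaminated
epochs, rater heterogeneity in bias/noise/experience, and CS-driven
acceptance. It does not emulate: realistic spatial topography (the
multi-channel continuous mode injects one template with fixed channel
gains and is only a pipeline exerciser), rater learning within or across
sessions, non-Gaussian label errors, or correlated rater errors. Passing
tests therefore demonstrate that the *measurement and analysis chain* is
correct and calibrated — not that real experts behave like the simulated
ones.

One emergent behaviour worth naming: at the calibrated (deliberately low)
morphology similarity, PN localisation on subset averages is itself a
substantial error source, so default-scale ICCs sit well below the values
clean data would give, and conditions with lower CS give lower ICCs. That
ordering — morphology similarity driving label reliability — is the
phenomenon the pipeline exists to quantify.

## Problem sizes

The shipped analyses and tests use the study's own design sizes (30
datasets × 50 epochs, 5 raters × 3 sessions) for end-to-end runs;
statistical calibration checks use 100–1000 replicates at those or smaller
matrix sizes (e.g. 300 replicates for ICC coverage, 100 GLMM refits for
trend recovery, 1000 fast logistic refits for LRT type-I error), chosen so
each check resolves its target tolerance comfortably.

## Known limitations

* The F-based CI is approximate; coverage was verified at the study size
  but will degrade for very small n or strongly negative estimates.
* The single dataset-level random intercept understates the true crossed
  dependence (rater, session); trend standard errors are accordingly
  approximate.
* EDF input is not supported; continuous recordings enter as delimited text
  with a known sampling rate.
* The artefact model is a single blink-like transient with pragmatic
  defaults; no quantitative artefact taxonomy was available to fit.
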