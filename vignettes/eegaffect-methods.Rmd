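---
title: "Models and methods behind eegaffect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eegaffect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eegaffect` implements a complete analysis pipeline for time-varying
emotion recognition from multichannel EEG: feature extraction, wrapper
feature selection, three classifier families, and four cross-validation
frameworks that differ in what the trained model is allowed to have seen.
This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions that were
genuinely open — in enough detail that a maintainer could re-derive every
behaviour from this document and the tests.

## The data model

The unit of analysis is a 20-second, 14-channel EEG window recorded at
128 Hz (a 14 × 2560 matrix) while a participant watches a long (14–24
minute) emotionally dynamic film. External annotators rate the
participant's valence (unpleasant → pleasant) and arousal (passive →
active) on continuous scales once per non-overlapping 20-s period.
Labels are binarized at the zero affect threshold: the combined
continuous value maps to "high" iff it is strictly positive.

Three conventions the upstream description of such data leaves open are
fixed here:

* **Annotator combination.** The per-period ratings of the available
  annotators are combined by arithmetic mean before thresholding
  (`binarize_labels(combine = "mean")`). A majority-vote-on-binarized
  alternative is provided and flagged; the mean is the default because
  the threshold rule operates on a single combined continuous value.
  A missing single-annotator entry simply drops out of the mean;
  participants missing whole movies are handled by the exclusion rules.
* **Exact zero.** A combined value of exactly zero maps to "low". Only
  strictly positive values are "high"; a deterministic tie rule is
  required and this is the conservative one.
* **Window/label alignment.** Annotation period *k* (1-based) covers
  samples `[(k−1)·20·fs + 1, k·20·fs]` — half-open in time, explicit in
  code. The first and last periods of every movie are discarded, and the
  discard removes both the label *and* the EEG, so a movie with *P*
  periods yields exactly *P − 2* contiguous windows. This is asserted as
  an invariant.

Participant exclusion mirrors the structure of a real 40-participant
study: participants with no annotated movies are always removed;
frameworks that need complete per-participant data (LOMO-Within, LOPMO)
also remove participants with partially missing movies; LOMO-Within
additionally removes participants whose minority-class count for the
target is below `min_minority = 10`, because a per-participant model with
fewer than ten minority windows cannot be meaningfully evaluated.

Cohorts serialize to a plain-text directory (JSON layout, CSV roster,
window metadata, and sample table). Doubles are written as `%.17g` and
parsed with `strtod`, so a write/read cycle is bit-exact — an invariant
the test suite checks window by window.

## The 217 features

For each window, each channel contributes:

* **Band log-powers (70).** Welch spectra with 128-sample (1 s) Hann
  segments and 50% overlap give a 1 Hz grid; the band feature is
  `log( 1/(f_high − f_low) · Σ X[f] )` with the sum inclusive of both
  edge bins. The normalizer is the band width even though the inclusive
  bin count is one larger — the formula is implemented literally, and tests pin e.g. the flat-spectrum value
  `log(3/2)` for the (8, 10) band. Band edges: theta (4, 8), slow alpha
  (8, 10) — the one band pinned externally — alpha (8, 13), beta
  (13, 30), gamma (30, 45), all configurable. Natural logs everywhere; a
  floor of `eps = 1e-12` on the band average keeps constant signals
  finite rather than erroring.
* **Asymmetries (35).** `PSD(left) − PSD(right)` per band over the seven
  symmetric pairs, labelled by lobe (AF, F, F34, FC, T, P, O) — the only
  pairing consistent with a 14-channel layout and 35 asymmetry features.
* **Nonlinear/time-domain descriptors (112 = 14 × 8).** Hjorth mobility
  `sqrt(var(Δx)/var(x))` and complexity `HM(Δx)/HM(x)` (first differences
  as the derivative); the DFA exponent (slope of log RMS fluctuation of
  the linearly detrended integrated profile over ~12 log-spaced box sizes
  in `[4, n/4]`); the Petrosian fractal dimension
  `log10(n) / (log10(n) + log10(n/(n + 0.4·N_δ)))` with `N_δ` the number
  of sign changes of the first difference; the Higuchi fractal dimension
  (slope of `log L(k)` vs `log(1/k)` for `k = 1..k_max`, `k_max = 8`);
  spectral entropy (Shannon entropy of the normalized Welch PSD over
  `log(n_bins)`, in [0, 1]); SVD entropy and Fisher information of the
  normalized singular values of the delay-embedding matrix with
  `(dim, delay) = (10, 1)`.

Where a parameterization is not pinned externally (Higuchi `k_max`, DFA
box sizes, the embedding), common reference-implementation defaults were
chosen once, are configurable through `feature_params()`, and are
attached to every feature matrix as attributes.

Expected scale behaviour is tested per family: under `x → c·x` the band
log-powers shift by the additive constant `2·log c`, asymmetries and all
112 nonlinear descriptors are invariant. Canonical signals anchor the
implementations: a ramp has Petrosian dimension exactly 1 and Higuchi
dimension ≈ 1; white noise has Higuchi dimension ≈ 2, DFA ≈ 0.5, Hjorth
mobility ≈ √2 and complexity ≈ √(3/2); Brownian motion has DFA ≈ 1.5; a
sampled 1 Hz sinusoid has mobility `2·sin(π/128)`.

## Wrapper selection

`sfs()` grows a feature set greedily from empty, `sbs()` shrinks it from
the full candidate set; both score a candidate set as the unweighted mean
positive-class F1 across the folds of the chosen cross-validation
framework, with features z-scored on each fold's training rows only (a
leakage guard the selection objective itself needs). Ties break to the
earliest candidate in registry order, and among equal best scores the
smaller set wins — determinism matters more than the particular choice.

Scoring selection on the same outer folds that are later reported (the
default, `selection_mode = "outer"`) matches the protocol implied by
reporting best test F1 against feature count, but it is optimistically
biased; a nested mode that reruns selection inside each training fold on
stratified inner splits is provided and flagged in the result metadata.
Neither mode is asserted to be "the" correct reading — both exist
because the choice is genuinely open.

Greedy wrapper search is quadratic in the candidate count, so
`max_steps` and `feature_subset` cap the sweep for tractable runs; the
capped sweep is a documented deviation from the full 217-feature path.
For candidate sets of six or fewer features the traces are verified
step-for-step against an independently coded naive greedy search, and a
deliberately constructed linearly-coupled pair (informative only jointly,
each member swamped by a shared nuisance) shows the expected asymmetry:
backward selection retains the pair, forward selection's first step
cannot rank it above a weak marginal feature.

## Classifiers

LDA (`MASS::lda`) and the linear-kernel SVM (`e1071::svm`, cost 1, no
class weights) consume the feature matrix, z-scored with training-fold
statistics. The convolutional LSTM consumes raw per-channel-z-scored
windows through: conv1d (64 filters, length 10) → max-pool 3 → conv1d
(128 filters, length 5) → max-pool 3 → LSTM (256 units, last hidden
state) → dense 256 → dense 128 → dense 1 with sigmoid, trained with
binary cross-entropy at initial learning rate 1e-3. Details the
architecture description leaves open were fixed minimally: Adam, stride-1
unpadded convolutions, pooling stride equal to pool size, 30 epochs and
minibatch 32 by default, decision threshold 0.5; all are recorded in the
model object. The network is implemented in-package directly on BLAS
matrix operations (im2col convolutions, full backpropagation through
time), which keeps training exactly reproducible from a seed; gradients
are verified against finite differences and each layer's parameter count
against hand arithmetic (9024 / 41088 / 394240 / 65792 / 32896 / 129).

## Cross-validation frameworks and metrics

Four fold generators cover the known/unknown subject × known/unknown
stimulus grid: LOPO (one fold per participant), LOMO-Inter (one per
movie, participants pooled), LOMO-Within (per-participant models, one
fold per movie), and LOPMO (one fold per participant × movie cell;
training excludes *all* data of the test participant and *all* data of
the test movie). Every generated fold passes hard leakage assertions
(`check_folds()`), and the partition properties are tested.

Metrics are positive-class precision, recall and F1 with "high" as the
positive class; a macro-averaged F1 mode exists and is flagged in the
metadata, because the single-positive-class convention is standard for
imbalance-sensitive reporting but not the only defensible one. Zero-denominator cases return 0
with a warning — extreme-imbalance folds make them unavoidable. Folds
whose training windows contain a single class are skipped with a
warning and excluded from the (unweighted) fold mean. Fold-score
distributions are compared by a Kolmogorov–Smirnov normality check on
standardized scores (approximate, since mean and SD are estimated from
the same scores — the report says so) followed by the Kruskal–Wallis
H-test at α = 0.05.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable with known
ground truth. It is an additive signal model, not a biophysical one: per
(participant, movie), latent binary valence and arousal states follow a
two-state Markov chain (per-movie stationary "high" probability,
persistence ρ — the next state copies the previous with probability ρ,
else redraws from the stationary law); each 20-s period of each channel
is 1/f^β coloured noise (β default 1) plus, on designated channels,
band-limited oscillations whose log-power shifts by the planted effect
size in the high state, plus optional spectral-slope shifts; per-channel
log-amplitude random effects for participants (SD 0.2) and movies
(SD 0.1) supply inter-subject and inter-stimulus nuisance; three
annotators report the state as ±0.5 plus Gaussian noise (SD 0.1) with
independent sign flips (default probability 0.1). This spans exactly the
feature families the extractor measures — spectral, roughness/fractal,
complexity — which is the point; it does not emulate artifacts,
nonstationary spectra within a state, or social viewing conditions, so
passing tests demonstrate pipeline correctness and calibration, not
real-data performance.

Presets fix the study conditions used by tests and the acceptance
script:

* `mini` — 8 participants × 4 movies × 40 periods, with imbalanced
  per-movie stationary probabilities emulating the real stimuli (one
  movie ~79%/57% high valence/arousal, one ~3%/2%).
* `chance` — 6 × 4 × 22 periods with *every* state-dependent and
  nuisance term switched off: zero planted effects, zero annotator
  flips, zero participant/movie random effects, balanced stationary
  probabilities and weak persistence (0.4). Each of these is part of
  what "chance calibration" means. Strong persistence over few periods
  makes the realized class fraction of a short movie drift far from ½;
  and participant-level amplitude effects shift all of a held-out
  subject's features coherently relative to the training boundary, so
  per-fold predictions collapse toward one class and the positive-class
  F1 of a signal-free classifier falls well *below* ½ — subject-level
  covariate shift, not leakage. Both would make the calibration measure
  something other than the evaluation machinery. The nuisance case is
  covered by its own invariant instead: with participant effects on and
  class effects off, leave-one-person-out F1 must stay at or below
  chance (nothing about subject identity may leak into the labels). The
  calibration classifier is the linear SVM; LDA in the p ≈ n regime
  (217 features against a few hundred training rows) degenerates in a
  way the SVM does not, which is also why per-participant models with
  the full feature set are unreliable in general.
* `planted` — the same shape with a strong (1.5 log-units) T7/T8 gamma
  power effect plus a spectral-slope shift on the same channels and
  clean labels; LOPO recovers it at F1 > 0.9 and forward selection's
  first pick lands on a planted channel in ≥ 90% of seeds.

Annotator flip probabilities map to pairwise agreement as
`(1−p)² + p²`; solving for 0.75 gives p ≈ 0.146, and the acceptance
script measures the realized agreement at that setting.

## Problem sizes and numerical choices

The default test and acceptance runs use deliberately small cohorts —
tens to hundreds of windows, two generator seeds for the chance
calibration, ten seeds for recovery rates, twenty replicates for the
fractal/DFA Monte-Carlo anchors, 200 replicates for the Kruskal–Wallis
null — sizes chosen so the whole suite exercises every code path in
minutes on a single core while keeping Monte-Carlo tolerances honest
(each tolerance is at least ~3 SE of the statistic under the stated
size). Degenerate inputs are handled explicitly: constant signals error
in Hjorth/Higuchi/DFA ("degenerate signal") but not in band powers
(the `eps` floor); rank-zero embeddings error; zero in-band power is
floored; single-class training folds error at the classifier level and
are skipped with a warning at the experiment level.

## Known limitations

* The generator's oscillations are near-sinusoidal; real EEG band power
  is broadband and nonstationary within a window.
* The outer-fold selection objective is optimistically
  biased by construction; use the nested mode when reporting
  generalization claims.
* LDA with the full 217-feature set is unreliable whenever training
  folds are small (LOMO-Within especially); prefer the SVM or a feature
  subset there.
* The CLSTM is a faithful but compact implementation; it trains
  full-scale but is intended for desk-scale experiments, not GPU-scale
  sweeps.
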