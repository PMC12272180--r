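---
title: "Methods: simulating and analyzing dual-task working-memory interference"
author: "dualtaskr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing dual-task working-memory interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtaskr)
```

## The experiment this package models

`dualtaskr` simulates and analyzes a dual-task paradigm in which a
participant encodes a sequence of four auditory or visual stimuli into
working memory (WM), retains it for 5.5 s, and then compares it to a probe
sequence. The to-be-remembered feature is either *temporal* (the pattern of
short/long inter-stimulus intervals) or *spatial* (the stimulus locations),
giving four WM conditions (auditory/visual x temporal/spatial). On two
thirds of trials an *intervening* auditory judgment — which of two intervals
was longer (temporal variant) or whether the middle sound came from the
left or right (spatial variant) — interrupts the retention period, starting
2 s after the offset of the last encoding stimulus. Behavioral errors,
pupil diameter (an index of effort), stimulus-locked EEG potentials (the P2
in particular) and parietal alpha-band oscillations are the measures of
interference between the two tasks.

The package has two halves:

* a **generator** (`experiment_config()`, `generate_design()`,
  `generate_stimuli()`, `simulate_behavior()`, `simulate_pupil_trial()`,
  `simulate_eeg_trial()`) that produces synthetic data with the statistical
  structure the analyses assume, and
* the **analysis stages**: pupil cleaning (`detect_blinks()`,
  `interpolate_blinks()`, `reject_trials()`, `zscore_concatenated()`),
  paired permutation tests (`permutation_null()`, `significant_runs()`,
  `windowed_percentile_test()`), the ERP chain (`preprocess_eeg()`,
  `epoch_and_reject()`, `extract_p2()`, `rm_anova()`), time-frequency
  analysis (`mirror_pad()`, `morlet_tfr()`, `db_baseline()`,
  `individual_alpha()`, `alpha_contrasts()`) and behavioral mixed models
  (`fit_glmm()`, `anova_on_coefficients()`, `cycle_baselines()`,
  `holm_bonferroni()`).

Because every stage can be run against the generator, every stage is
testable without any original recordings.

## The design generator

`generate_design()` reproduces the blocked structure: blocks of 20 trials
holding one condition cell (WM modality x WM domain x intervening
condition) constant, half *same* and half *different* trials in random
order, 40 trials per cell in total, every cell appearing once per cycle
before any repeats, no cell occupying two adjacent blocks, and auditory and
visual WM cells scheduled in separate sessions. Scheduling resamples each
cycle's permutation until the boundary constraint holds, with a bounded
number of attempts.

Stimulus sequences use the modality-specific interval sets (auditory
200/340 ms, visual 200/580 ms; the difference is fixed at 140 and 380 ms by
construction), five loudspeaker azimuths or twelve circular patch
positions, and a fixed first position (central loudspeaker, top-center
patch) so that both domains carry three items. Auditory-spatial WM
sequences are isochronous at the long interval. Intervening sequences place
three noise bursts at azimuths −4° and 0° in an A-B-A pattern; one of the
two intervals, chosen at random, is longer.

Two points are underdetermined by the description we emulate and were
decided once:

* **Interval jitter.** Only the means (370 and 550 ms) and their 180 ms
  difference are stated. We jitter each interval independently and
  uniformly by ±60 ms around its mean: bounded, mean-preserving, and the
  short and long ranges can never overlap, so the correct answer is always
  well defined.
* **Unattended-domain changes.** The probability that the unattended
  feature changes between encoding and probe is unstated; the default is
  0.5, configurable in `generate_wm_sequences()`.

## The behavioral observer

`simulate_behavior()` draws errors from a logistic model: per-cell fixed
error log-odds plus a participant random intercept (SD 0.5) and a random
slope on intervening-task presence (SD 0.3), all on the log-odds scale.
Default cell log-odds encode the qualitative structure the analyses look
for: better WM performance when modality suits domain (auditory-temporal,
visual-spatial), interference from the auditory intervening tasks
concentrated on auditory-temporal WM (a log-odds shift of +1.0 for the
matched cell), an easier spatial than temporal intervening judgment, and
elevated intervening-task errors under matched auditory WM load. These
effect sizes are free parameters of the generator, not measurements; they
are chosen to be realistic for error rates in the 0.1–0.4 range. A
`guessing_observer()` (all log-odds zero, no random effects) errs with
probability 0.5, the chance level for the same/different judgment.

## The pupil model and cleaning pipeline

Traces are sampled at 500 Hz from the start of the 1.5 s baseline to the
sample immediately before probe onset, with time zero at the offset of the
final encoding stimulus. The trace is a constant baseline (arbitrary
tracker units, default 1000) plus a gamma-shaped impulse response
(`h(t) = (t/t_max)^s exp(s(1 - t/t_max))`, `t_max` = 1.1 s, `s` = 10.1)
convolved with stimulus onsets and scaled per condition cell. With these
kernel parameters the summed response to a four-stimulus encoding sequence
peaks roughly 0.7 s after encoding offset, the latency typical of
task-evoked dilations. Auditory-temporal WM cells add a linear anticipatory
ramp toward intervening onset. Blinks arrive as a Poisson process (default
0.15 events/s, 0.1–0.3 s long) and drop the signal to zero with two-sample
flanks — the loss-of-pupil signature of an eyetracker — so that the
velocity/acceleration detectors are genuinely exercised.

Cleaning follows the four-step recipe: detect, interpolate, reject,
normalize. Detection thresholds are overridable; since the original
per-session thresholds are unknowable, the defaults are derived from each
trace: velocity and acceleration limits at 3x the 0.995 quantile of the
trace's own absolute first/second differences, and position bounds at
median ± max(5 MAD, half the median). Both rules were chosen so that slow
task-evoked dilations never trip them (median- or MAD-only rules do, on
low-noise traces, because the flat baseline dominates the statistics) while
dropout flanks — orders of magnitude faster — and near-zero samples always
do. Manual segment marking is replaced by the `extra_mask` argument, a
machine-readable list of additional samples to mask.

Interpolation replaces interior masked segments with the line joining the
mean of the three clean samples on each side; segments touching a window
edge are filled by projecting a least-squares line fit to the five adjacent
clean samples (the linear-fit method is our choice; only "linear fit" is
specified). Trials with more than 25% masked samples are rejected — the
bound is strict, exactly 25% is kept. Z-scoring concatenates all of a
participant's kept trials across sessions, normalizes with the population
SD convention (the concatenation *is* the normalization population), and
splits back; the output is therefore invariant to positive affine
rescalings of raw diameter, which is why only relative pupil size is ever
interpreted.

## Permutation testing

Condition contrasts are paired across participants. `pointwise_paired_t()`
computes the paired t statistic per time point (zero-variance points yield
±Inf, never NaN). The null is built by flipping each participant's
condition labels — equivalently the sign of the paired difference — 2000
times by default; p-values are two-sided on |t| with add-one smoothing,
`p = (#{|t_null| >= |t_obs|} + 1)/(n_iter + 1)`. Two-sidedness is a
deliberate reading of an ambiguous verbal rule: both positive and negative
condition differences are reported by the analyses this package supports.
One-sided tests and retention of the full null matrix are available through
arguments. An `exhaustive = TRUE` mode enumerates all `2^n` sign patterns
and is the oracle the Monte-Carlo path is tested against.

Two decision criteria are provided: the run-length rule (pointwise p <
0.05 for at least 15 consecutive samples; `significant_runs()`) used for
pupil time courses, and the windowed percentile rule (|t| above the 95th
percentile of its own null within a time region of interest;
`windowed_percentile_test()`) used for alpha power, with windows [2, 3.5)
and [3.5, 5) s. Windows are half-open in seconds, which makes sample
counting unambiguous (750 samples per 1.5 s window at 500 Hz). The
procedure is pointwise with a run-length option rather than cluster-mass
based: that is the operational definition we implement.

## The EEG model and ERP chain

Synthetic EEG superimposes (a) ERP templates — Gaussian-windowed N1
(100 ms, −4 µV), P2 (205 ms, +5 µV) and P3 (320 ms, +3 µV) components with
fronto-central/parietal topographies — at every stimulus onset, the P2 of
intervening-task stimuli scaled per condition cell (smaller when WM content
overlaps the intervening task in modality, and for the spatial task in
domain); (b) an alpha sinusoid at the participant's individual alpha
frequency (integer 8–12 Hz), random phase per trial, strongest at Pz, with
a per-phase envelope (elevated during auditory-WM retention, suppressed
then recovering for visual WM) and a transient suppression while an
intervening task runs; and (c) 1/f background noise per channel. Mastoid
channels carry only attenuated noise. A configurable fraction of stimulus
epochs receives a 150 µV transient. EEG is synthesized directly at 256 Hz
by default for speed; a 2048 Hz mode exercises the decimating downsampler.

Preprocessing downsamples to 256 Hz, re-references to the mastoid average,
and band-pass filters 0.5–20 Hz with a zero-phase linear-phase FIR applied
by centered convolution on a reflection-padded signal. The default
transition width is 0.5 Hz (about 1690 taps at 256 Hz), chosen so the
steady-state gain at 0 Hz is effectively zero while the filter remains much
shorter than the continuous segments analyzed; narrower transitions are
configurable but pointless at these segment lengths. Epochs span −100 to
+500 ms; any channel exceeding 100 µV peak-to-peak rejects the epoch (the
comparison is strict: exactly 100 µV survives), and survivors are
baseline-corrected on the half-open [−100, 0) ms window. Ocular-artifact
decomposition is a pluggable no-op: the generator produces no ocular
components, and an external ICA can be slotted in front of epoching.

P2 amplitude is the mean over 190–220 ms and the fronto-central cluster
(Fz, FCz, Cz, FC1, FC2), computed from intervening-onset ERPs. `rm_anova()`
fits the fully-within repeated-measures ANOVA (one error stratum per
within-participant term) for the three factors WM modality, WM domain and
intervening-task domain, reporting F, p, classical η² and generalized η² —
both variants are reported because the η² flavor in the emulated analysis
is unspecified. Follow-up ANOVAs restricted to one WM modality are the same
call on a subset, assessed against a Holm-adjusted α (0.017 for three
follow-ups).

## Time-frequency analysis

For oscillatory analysis the participant-average ERP (per trial phase,
condition and sequence position) is subtracted at each stimulus timestamp —
plain average subtraction, per the operational description, not a
regression — and whole-trial epochs are mirror-padded with their reversed
first and last 5 s before the continuous Morlet transform (fixed 5-cycle
Gaussian envelope at every frequency, 1 Hz steps; "width in cycles" is read
as a constant cycle count). The transform is FFT-based convolution with
unit-energy wavelets and is tested against a direct time-domain convolution
oracle to a relative error of 1e-6. Power is expressed as dB change,
`10 log10(P / P_baseline)`, against the per-participant baseline power
averaged across *all* conditions before any condition split — so the
baseline, and every dB value, is invariant to permuting condition labels.

The individual alpha frequency (IAF) is the integer frequency in 8–12 Hz
with the largest absolute mean dB change at Pz over the retention window
trimmed by 500 ms at each edge (the absolute value matters because the
direction of alpha change flips with WM modality); ties break to the lower
frequency. The alpha time course is the mean over IAF ± 1 Hz. Contrasts
between intervening conditions run the windowed percentile test in the
[2, 3.5) and [3.5, 5) s regions, on domain-collapsed per-participant time
courses.

A structural note on IAF recovery: with a fixed 5-cycle wavelet the
spectral bandwidth at 10 Hz is ±2 Hz, so a pure sinusoid bleeds heavily
into neighboring 1 Hz bins. In the noise-free limit the *change* profile
across bins is flat (numerator and denominator scale identically) and the
argmax is undefined; it is the background noise floor that localizes the
change at the true frequency. Recovery is therefore assessed at the
generator's default noise level with trial-averaged power maps (24 trials
per estimate in the test suite), which recovers the injected frequency
essentially always; single-trial maps or unrealistically quiet noise floors
do not, and real analyses do not use them either.

## Behavioral mixed models

`fit_glmm()` fits the two logistic mixed models by treatment coding with
configurable baselines (defaults: auditory, temporal, none): intervening
errors on WM condition (4 levels) crossed with intervening task, WM errors
on WM modality x WM domain x intervening condition, both with
per-participant random intercepts and slopes. The random structure
simplifies stepwise on nonconvergence (correlated slopes → uncorrelated →
intercept-only → fixed-effects-only when random effects are unestimable),
each step reported, never silent. Separation (an all-0/all-1 cell) is
reported with the offending cell. Omnibus tests per term are type-III Wald
χ² via `car::Anova` — matching the χ² reporting convention for this model
class; Satterthwaite degrees of freedom apply to linear mixed models and
would be used automatically there, but are not defined for the binomial
fits. `cycle_baselines()` re-fits under rotated baseline assignments until
a first-order coefficient exists for every requested simple-effect pair
(within-WM-condition intervening contrasts; within-intervening-task WM
contrasts), caching fits per assignment, and `holm_bonferroni()` applies
the step-down correction at a familywise α of 0.05.

## Numerical choices and degenerate inputs

* Zero-variance difference series give ±Inf t statistics, and permutation
  comparisons back the observed |t| off by one part in 10^10 so that the
  identity sign pattern always counts as "at least as large" despite
  floating-point summation-order differences.
* An ANOVA term with zero effect variance reports F = 0, p = 1 rather than
  0/0.
* A constant pupil trace yields an empty blink mask; a constant
  concatenation is a z-scoring error.
* Blink segments without enough clean anchor samples (3 interior, 5 at an
  edge) mark the trace unrecoverable instead of inventing data.
* All simulator randomness derives from one integer seed through a string
  hash (`participant`, `stream` labels), so any subset of the simulation is
  reproducible in isolation.

## What the generator does and does not emulate

The generator reproduces the design constraints, timing, chance levels,
interference structure, pupil dilation dynamics with realistic blink
occlusion, ERP component structure with condition-scaled P2, and
phase-specific alpha dynamics at an individual frequency over a 1/f floor.
It does not emulate: psychoacoustic or photometric stimulus detail
(luminance values do not affect any analyzed quantity), ocular EEG
artifacts and their ICA topographies, eyetracker calibration drift,
session-level nonstationarities, or trial-to-trial ERP latency variability.
Green tests therefore certify the *pipeline* — that each stage computes
what it claims on data with the assumed structure — not that the assumed
structure exhausts real recordings.

## Problem sizes used by the test suite

The suite favors the smallest sizes at which each property is decisive:
design checks over 150 seeds; 10,000 intervening sequences and ~10,000
guessing-observer trials for the chance-level checks; exhaustive
permutation oracles at n ≤ 10 participants; 50 replicates for null
calibration and for the parameter-recovery studies (coefficient coverage
with an intercept-only observer and matched fit, measurement-level P2
tables at n = 20); and 20 IAF-recovery runs of 24 trials each. These are
the package's own desk-scale choices; all of them are ordinary function
arguments and scale up freely.
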