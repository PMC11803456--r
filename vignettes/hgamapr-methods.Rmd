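---
title: "Methods: high-gamma mapping and repetition attenuation"
author: "hgamapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-gamma mapping and repetition attenuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgamapr)
```

## The problem

Electrocorticographic (ECoG) functional mapping localizes eloquent cortex by
contrasting task and rest periods of a block-design paradigm. The biomarker
is high-gamma activity (HGA): broadband power in roughly 60–170 Hz, a proxy
for local population firing. Because the paradigm repeats the same movement
many times, repetition suppression can attenuate the response over the
session — within a block of consecutive movements (short-term) and across
blocks separated by rest (long-term). `hgamapr` implements the complete
analysis chain for such experiments and pairs it with a synthetic generator
that plants known responses and attenuation profiles, so that every stage
can be validated against ground truth without patient data.

## Paradigm model

A session is described parametrically by `paradigm_spec()`: a 10-s
pre-session rest, then 10 blocks, each a 12-s rest phase followed by 10
grasping trials of 0.6 s close cue + 0.6 s open cue. The defaults give a
250-s session with 100 trials. All durations are constrained to the 100-ms
epoch grid, so cue onsets align exactly with epoch boundaries — epoch
alignment is exact by construction, not by rounding. A *trial* is one
close+open pair; its evaluation window, 0.4–1.0 s after the close cue
(six 100-ms epochs), targets the hand-closing response.

Two groupings quantify attenuation: trial positions 1–3/4–6/7–9 form the
"nonresting" groups NR1–3 (short-term; within-block), blocks 1–3/4–6/7–9
form the "resting" groups R1–3 (long-term; across blocks). The 10th trial
of every block and the 10th block are excluded from the grouped pools to
balance the subgroups: each NR group then holds 3 positions × 10 blocks
= 30 samples per electrode, each R group 3 blocks × 9 trials = 27. (The
group *label* of a 10th trial is still defined — `assign_groups(5, 10)`
reports R2 — but such trials never enter the grouped pools.) The source
cohort's published per-group counts are three times these design counts;
since this pipeline draws exactly one window-mean sample per trial, both
counts are carried in the result metadata rather than forced to agree.

## Signal chain

The preprocessing order is fixed: drift removal → common average reference
→ band-pass → Hilbert envelope → downsampling → 100-ms log band-power →
rest z-scoring.

* **Drift removal** — 2 Hz high-pass, 4th-order Butterworth.
* **Common average reference (CAR)** — per sample, the mean over included
  channels is subtracted from each included channel; ground/bad channels
  are passed through and never enter the average or any statistic.
* **High-gamma band-pass** — 4th-order Butterworth high-pass at 60 Hz
  cascaded with a 4th-order low-pass at 170 Hz.
* **Envelope** — magnitude of the analytic signal (FFT method) at the
  native rate, then reduced to 400 Hz by averaging non-overlapping groups
  of `fs/400` samples. Block averaging doubles as the anti-alias step; for
  a nonnegative envelope it is unbiased and phase-free.
* **Epoching** — per 100-ms epoch, power is the mean squared envelope over
  its 40 samples, then natural-log transformed to approximate Gaussianity.
  Epoch indexing is 0-based with half-open intervals, documented in every
  output table. A trailing partial epoch is dropped.
* **Standardization** — per channel, z-scores against the mean and sample
  SD (n−1) of all epochs inside the ten 12-s rest phases. The 10-s
  pre-session rest precedes the block structure and is excluded; no guard
  band is applied. By construction the pooled rest epochs have mean 0 and
  sample SD 1 (asserted to 1e-9 in the tests).

**Filter causality.** All filters run as a single causal pass by default.
The cascade's group delay (≈5–8 ms at band center) is an order of magnitude
below the 100-ms epoch resolution, so the 0.3/0.7-s response landmarks are
unaffected, and a causal chain matches how clinical mapping amplifiers
process the signal online. It also keeps the analytic passband contract
tight: the causal 60/170 Hz cascade passes a 100-Hz tone at 98.8% RMS,
whereas a zero-phase (forward–backward) chain applies every magnitude twice
and passes it at only 97.6%. A `zero_phase = TRUE` argument provides the
offline convention; the magnitude tests cover both.

**Multiple runs.** When a patient contributes several runs, each run is
preprocessed and z-scored against its own rest phases; runs are then
concatenated at the trial-sample level (the `trial_samples()` constructor
accepts stacked blocks).

## Electrode significance

"Resting trials" are constructed by tiling each 12-s rest phase with
contiguous 1.2-s pseudo-trials scored by the identical 0.4–1.0 s window —
100 rest samples per electrode under defaults, symmetric with the 100
movement trials. Per electrode, a two-sided pooled-variance Student t-test
(df `n1+n2−2`) compares movement against rest window means; p-values are
Bonferroni-corrected by the number of recorded, non-excluded electrodes in
the case (read literally; the count of region-of-interest electrodes is
also emitted in metadata). An electrode is *significant* iff it lies in the
sensorimotor region of interest (precentral or postcentral gyrus label) and
its corrected p is below 0.05.

## Attenuation statistics

All attenuation tests are rank-based. The omnibus is the tie-corrected
Kruskal–Wallis H with a chi-square reference (k−1 df); completely tied
input returns H = 0, p = 1. Post hoc comparisons use Dunn's test:

z = (R̄ᵢ − R̄ⱼ) / sqrt[(N(N+1)/12 − Σ(t³−t)/(12(N−1))) (1/nᵢ + 1/nⱼ)]

with two-sided normal p-values, Bonferroni-adjusted by the declared family
size — 9 for the consecutive-position family (1,2)…(9,10), 3 for the NR or
R pairwise family. The chi-square omnibus approximation is used at all
sample sizes; the cohort pools here are large (hundreds of samples), where
it is accurate.

* **Cohort curves** (`consecutive_position_test`): one window-mean sample
  per (significant electrode × block) for each trial position — with 60
  significant electrodes, 600 samples per position, and likewise per block.
  Electrodes are pooled flat, without patient weighting.
* **Per-electrode classification** (`classify_attenuation`): an electrode
  is *short-term attenuated* iff the Dunn-adjusted NR1-vs-NR3 p is below
  0.05 **and** the NR3 mean rank lies below NR1 — a two-sided test plus a
  direction check, matching common Dunn's-test software, rather than a
  one-sided test. Long-term attenuation is the R1-vs-R3 analogue.
  Degenerate (all-tied) electrodes are classified not-attenuated and
  flagged.
* **Temporal dynamics** (`temporal_dynamics`): mean ± 2 SEM per 100-ms step
  from −0.2 to +1.2 s around the cue, for trial 1 vs trial 9, merged NR1 vs
  NR3, and block 1 vs block 10.
* **Baseline drift** (`baseline_drift_test`): pooled rest z of blocks 1–3
  vs 7–9, two-sided Mann–Whitney U.

The Mann–Whitney implementation uses exact enumeration when the pooled
sample has at most 12 tie-free observations, and otherwise the normal
approximation with tie and continuity correction. Exhaustive computation
over every achievable U at 6-vs-6 shows the approximation is within 0.0062
of the exact two-sided p wherever the exact p ≤ 0.2, and within 0.016
everywhere (the worst case sits near p ≈ 0.5, where no decision changes);
the tests assert exactly this analytic property.

## Spatial analysis

Electrode tables carry MNI152 RAS millimetre coordinates. The hand-knob
reference point ("sigma", the deepest point of the inverted-omega
precentral fold) is a configuration input per hemisphere — anatomy
pipelines are out of scope — with defaults (±36, −22, 54). Hemisphere
assignment follows the sign of x; x = 0 falls back to a configured default
with a warning. Over the significant electrodes, a 2×2 gyrus × attenuation
table is tested with Fisher's exact test (two-sided, sum of hypergeometric
probabilities no larger than the observed table's); the published analysis
does not print its table, so this construction is recorded as an
interpretation in the output metadata. Hand-knob distances of attenuated vs
non-attenuated electrodes are compared with the two-sided Mann–Whitney U.

## The synthetic generator

`generate_recording()` emulates the paradigm, not the brain: its purpose is
parameter recovery, so every planted effect is known exactly.

* **Background** — per channel, unit-variance 1/f^α noise (spectral shaping
  of white Gaussian noise, α = 1 by default), mixed as
  `(1−f_sh)·independent + f_sh·shared` with a shared fraction of 0.2;
  optional mains sinusoid; optional per-block background gain to plant
  baseline drift.
* **Bursts** — on responsive channels, each close cue adds band-limited
  noise (flat 60–170 Hz mask with 4-Hz half-cosine edges, ≥ 90% of power in
  band) shaped by a Gaussian envelope that peaks 0.7 s post-cue and first
  exceeds 5% of its peak at 0.3 s — the two landmarks the temporal dynamics
  are anchored to. The amplitude of the burst of trial t in block b is
  `burst_gain · s[t] · l[b]`.
* **Profiles** — the default short-term profile s decays from the first to
  the fifth trial, rebounds over trials 6–8 and dips at 9–10; the long-term
  profile l drops after block 1 and plateaus. `burst_gain = 0.222` and
  `s[9] = 0.66` were calibrated once so that the full pipeline's
  grand-average first-trial curve peaks near 1.25 z at 0.7 s with a ninth-
  trial peak near 0.66 z, and then frozen; the remaining values encode only
  the qualitative shape above.
* **Ground truth** — a channel is flagged planted-attenuated when the mean
  of its profile over the late third (positions 7–9) falls below the early
  third (1–3) by at least a 20% relative margin (configurable). A
  significance-based definition would not be a property of the
  configuration alone; the margin makes recovery tests well-posed. Under
  the default profiles the planted short-term drop is ≈ 17% — deliberately
  below the margin — so default channels are responsive but not flagged.

What the generator does *not* emulate: volume conduction and electrode
geometry, artifacts and epileptiform activity, non-stationary background
beyond the optional block gains, and any anatomy (region labels come from
the configured layout table). Passing recovery tests therefore demonstrate
that the statistics recover planted effects at realistic SNR, not that the
pipeline is robust to every clinical contingency.

## Numerical choices and degenerate inputs

* Sampling rates must be ≥ 1200 Hz and divisible by 400 (exact envelope
  decimation); band edges must lie below Nyquist.
* Zero epoch power makes the log undefined and raises an error naming the
  channel and epoch; zero rest variance likewise.
* Fewer than two included channels cannot be re-referenced.
* All-tied rank-test input yields H = 0, p = 1 rather than NaN.
* Report JSON contains no timestamps; identical configuration and seed
  reproduce byte-identical outputs (timings go to the log file only).

## Problem sizes used in validation

The shipped tests validate at sizes chosen to exercise the full design
while remaining desk-scale: one 52-channel default-SNR cohort (26 planted
responsive) for detection accuracy and the temporal landmarks; one
66-channel cohort (60 responsive) for the 600-sample pooling bookkeeping;
20 four-channel replicates for classification power under a planted 50%
short-term amplitude drop; and 200 sample-level null replicates for the
false-positive budget. Statistic implementations are checked against
enumeration and closed-form oracles on fixtures of at most 30 samples.

## Limitations

The pipeline consumes electrode coordinates and region labels as input;
cortical reconstruction, CT/MRI co-registration and surface projection are
out of scope, as are artifact rejection, sub-band spectral decomposition,
stimulation-based validation and any clinical interpretation. Cohort-level
pooling weights every electrode equally; patients with more significant
electrodes contribute proportionally more samples.
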