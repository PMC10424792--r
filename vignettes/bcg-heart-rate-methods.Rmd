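---
title: "Methods: heart-rate estimation from ballistocardiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate estimation from ballistocardiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bcgsleep)
```

## The measurement problem

A ballistocardiogram (BCG) records the micro-movements of the body caused by
the heart ejecting blood into the great vessels. A pressure-sensor belt under
the bedding measures it at 50 Hz without touching the sleeper, which makes it
attractive for long-term home monitoring — and makes the signal messy: it is
contaminated by respiration, posture shifts and movement, and the sensor
saturates outright when the subject tosses. The pipeline in this package
estimates per-window heart rate from that signal by two interchangeable
cores, an algorithmic J-peak detector and a small convolutional regressor,
and scores both against a pulse-oximeter photoplethysmogram (PPG), the usual
gold standard for heartbeats.

Both cores consume the same pre-elaborated input: the raw belt stream is
repaired, band-pass filtered to 2–10 Hz (the band holding the dominant BCG
waves), and cut into non-overlapping 400-sample windows — 8 seconds at
50 Hz, which at resting heart rates holds 5–8 beats. Eight seconds is long
enough for a stable mean inter-beat interval and short enough to track the
slow heart-rate wander of sleep.

## Pre-elaboration

**Repair.** Two defect classes are replaced by linear interpolation between
the nearest intact samples and flagged `repaired`: saturation runs (at least
`repair.sat_run_min = 3` consecutive samples pinned at an ADC limit) and
isolated spikes (robust z-score above `repair.spike_z = 5` against a 2 s
rolling median, scaled by the MAD of the residual). Interpolation keeps the
series smooth but invents no physiology, so windows whose defective fraction
exceeds `window.max_repaired_frac = 0.25` are excluded from analysis rather
than trusted. The quality mask, not the fill values, is the source of truth
downstream.

**Filtering.** The band-pass is a second-order digital Butterworth with
−3 dB points at 2 and 10 Hz, applied in forward (causal) form: a streaming
telemedicine deployment cannot look ahead, and nothing downstream depends on
the filter's phase (the evaluation never compares absolute beat positions
between belt and PPG, only per-window rates). The −3 dB property is a
consequence of the Butterworth design itself and is checked analytically
from the designed coefficients, which is direction-independent.

**Normalization.** Windows destined for the CNN are standardized to mean 0,
variance 1 *per window*, because the network consumes windows independently
and must not learn the belt's arbitrary gain or DC level. Zero-variance
windows cannot be standardized and are excluded with reason `flat`. The
algorithmic core does not need normalization: cubing and all comparisons are
scale-monotone, so its detections are invariant to positive rescaling (a
property the test suite asserts).

**PPG resampling.** The oximeter runs at 100 Hz; its stream is brought onto
the belt's 50 Hz timeline by linear interpolation, which with an exact 2:1
ratio reduces to taking every other sample and is exact on affine segments.
A resampled sample inherits a defect flag if either flanking source sample
carries one.

## The algorithmic core

Per non-excluded window:

1. **Cubing.** `x³` keeps the sign but enhances the large J deflection
   relative to everything smaller — the ratio of two cubed amplitudes is the
   cube of their ratio.
2. **Coarse envelope.** The cubed signal is low-pass filtered (second-order
   Butterworth) to one smooth bump per heartbeat; the bump maxima are the
   coarse IJK positions. The cutoff defaults to 6 Hz. The choice is
   constrained from both sides: it must stay below the intra-complex detail
   (the I-J-K alternation itself runs at ~8 Hz and must be smoothed away)
   but well above the heart-rate fundamental. We found the lower end of that
   range genuinely harmful: cubing compresses each beat into a burst only
   ~0.1 s wide, and a 2 Hz low-pass smears that burst into a bump several
   tenths of a second wide and nearly flat on top, so the triplet score —
   which reads its amplitudes from the coarse signal — can no longer
   separate the true complex from neighbouring fine-signal extrema. At 6 Hz
   the bump is narrow enough that the score decays decisively away from the
   burst centre. The envelope filter is applied zero-phase (forward and
   backward) so bump maxima stay aligned with the complexes; unlike the
   streaming band-pass, this stage already operates on a buffered window.
   Only coarse maxima reaching `jpeak.min_peak_frac = 0.1` of the window's
   largest coarse amplitude open a search span: cubing leaves genuine beats
   one to two orders of magnitude above noise-born wiggles, so a low
   relative threshold removes spurious spans without ever touching beats.
3. **Triplet scoring.** Within ±0.25 s of each qualifying coarse maximum
   (IJK width ≈ 0.12 s plus margin), every valley–peak–valley triplet of
   consecutive local extrema of the band-passed signal is scored
   `−a(I) + a(J) − a(K)` with amplitudes read at those positions in the
   coarse signal; the arg-max triplet's peak is the provisional J. Ties go
   to the earlier peak. A span holding fewer than three extrema simply
   yields no candidate.
4. **False-peak suppression.** Provisional Js closer together than the
   heartbeat interval cannot all be beats. A provisional J survives iff its
   band-passed amplitude is the largest among all provisional Js within
   ±0.5 s (non-maximum suppression over a 1 s span; equal amplitudes keep
   the earlier index). Survivors are therefore strictly increasing with
   gaps above 0.5 s. We chose sliding suppression over a tiled 1 s grid
   because tiling splits beats that straddle tile boundaries.
5. **Heart rate.** With `n ≥ 2` surviving Js, `HR = 60·Fs / mean(ΔJ)` bpm;
   fewer peaks, or a value outside the plausible 20–250 bpm range, yields
   the undefined sentinel (`NA`), and such windows are skipped by the
   evaluation with `m` reduced accordingly.

## The convolutional core

The regressor maps one normalized 400-sample window straight to a heart
rate. The architecture is eleven 1-D convolutions and nothing else: strided
convolutions do the temporal downsampling (no pooling), there are no dense
layers, and every convolution except the last is followed by batch
normalization and a leaky ReLU. The published description fixes the layer
count, those structural rules, the final single-filter kernel-1 layer, the
400 → 1 length collapse, and a total of 18.8 k parameters, but not the
per-layer table; the reference configuration here is reverse-engineered to
satisfy every constraint simultaneously:

| layers | channels | kernel | stride |
|--------|----------|--------|--------|
| L1 | 1 → 16 | 8 | 2 |
| L2–L9 | 16 → 16 | 8 | 2 |
| L10 | 16 → 16 | 7 | 1 |
| L11 | 16 → 1 | 1 | 1 |

Under same-padding (`out = ceiling(in / stride)`) the length chain is
400 → 200 → 100 → 50 → 25 → 13 → 7 → 4 → 2 → 1 → 1 → 1, and the parameter
count is 144 + 8·2064 + 1808 + 17 + 320 = 18,801 — 18.8 k to one decimal,
counting batch norm as two trainable parameters per channel (scale, shift)
and excluding running statistics. The receptive field covers the full
window from the sixth layer on, so the network can, in principle, see every
beat it needs. A `width_factor` multiplies all hidden channel counts for
capacity experiments; the default of 1 keeps the model lightweight, which
is the point of the design.

Training minimizes the mean squared error between the network output and
the z-normalized target heart rate, with Adam at its default parameters
(learning rate 0.001, β₁ = 0.9, β₂ = 0.999), an L2 penalty of 1e−4 on the
convolution kernels, leaky-ReLU negative slope 0.3, and batch size 64 (the
last three are conventional defaults, config-exposed). Exactly 30 epochs
are run with no early stopping and no checkpoint selection; the final state
is used. The target normalizer (mean, SD) is fitted on training subjects
only and inverted at prediction time. The train/test split is by subject —
two thirds training, one third held out, drawn before any optimization —
and the test suite asserts that no subject ever contributes windows to both
sides. Training targets default to the PPG-reference heart rate of the
paired window, as with real data; the simulator's exact truth can be
substituted via `cnn_targets = "ground_truth"`.

The network, its gradients and the optimizer are implemented directly in R
with im2col matrix algebra. At 18.8 k parameters this is entirely adequate
(a training batch is a handful of small matrix products), keeps the package
dependency-free on this front, and the backward pass is verified in the
test suite against central finite differences to ~1e-8 relative error.

## The PPG reference

Systolic peaks are local maxima that exceed the window median by at least
0.3× the window's (max − median) range — a median-relative criterion, so DC
offsets are irrelevant — and are separated by more than 0.33 s (≈180 bpm
ceiling); the larger peak wins a conflict, and minima serve only to
guarantee each accepted peak is a genuine turning point. The published
reference formula `HR = 60·Fs / Ns` leaves `Ns` ambiguous (a single "index
point" cannot yield a rate); the only reading consistent with the rest of
the pipeline is the mean inter-peak interval in samples per window, which
is what both cores use as well. Prominence 0.3 and the 0.33 s refractory
are our choices, config-exposed.

## The session simulator

No field-trial recordings are publicly deposited, so the package ships a
seeded generator whose defaults encode the documented study conditions, and
all recovery properties are asserted against its exact ground truth.

* **Beat times.** Inter-beat intervals are `60 / HR(t)` plus Gaussian
  jitter (SD 30 ms). `HR(t)` is a mean-reverting (Ornstein–Uhlenbeck-style)
  walk around the profile mean (default 55 bpm asleep; cohort draws uniform
  on 45–75) with stationary SD 5 bpm and a 60 s relaxation time, clamped to
  30–120 bpm. We preferred the OU walk to a sinusoidal modulation because
  it produces the aperiodic slow wander that actually stresses a per-window
  MAE, while zero wander and jitter collapse to an exact metronome, giving
  closed-form test cases.
* **BCG waveform.** Each beat contributes an IJK complex: Gaussian-windowed
  deflections (width ~20 ms) at −60 ms / 0 / +60 ms with amplitudes −0.4 /
  +1 / −0.5, so the complex's energy falls inside the 2–10 Hz passband. A
  sinusoidal respiration baseline (0.2–0.4 Hz, amplitude 3× the J peak) and
  white noise (SD 0.15× the J peak) are added. All amplitudes and widths
  are invented — the literature gives no canonical template — and
  config-exposed.
* **Artifacts.** Movement episodes arrive as a Poisson process (default 6
  events/hour, exponential durations with mean 100 s, together covering
  roughly 15–20 % of an overnight session) and replace the signal with a
  large random-walk transient clipped to the ADC limits, producing the
  flat-topped saturation runs the repair stage must find. Every span is
  guaranteed to touch a rail.
* **PPG.** One unimodal pulse per beat (raised-cosine upstroke, exponential
  decay) peaking 250 ms after the J-peak — the pulse arrival delay — plus
  mild noise.

Everything is a pure function of (profile, duration, seed); per-subject
seeds derive deterministically from one cohort seed, and cohort writes are
byte-reproducible.

**What the simulator does not model** — and therefore what passing tests do
*not* demonstrate about field data: posture-dependent morphology change,
talking and non-saturating movement noise, arrhythmia, power-line
interference, sensor drift, and packet loss coupled to motion. Synthetic
beats are morphologically homogeneous, so both cores score far better here
than any field trial would; the synthetic results validate the machinery
(shapes, contracts, convergence, recovery under the stated noise), not
clinical accuracy.

## Numerical choices and degenerate inputs

* Batch-norm uses variance floor 1e−3 and running-statistics momentum 0.99;
  inference uses running statistics, so prediction is deterministic.
* Glorot-uniform weight initialization, seeded; shuffling is seeded per
  epoch; two runs with the same seeds produce identical histories (pure R
  arithmetic, asserted in the suite).
* Plateaus in extrema detection collapse to their first sample; equal
  triplet scores keep the earlier J; equal suppression amplitudes keep the
  earlier index.
* An entirely defective recording cannot be repaired and errors out;
  a recording shorter than one window yields an empty window set with a
  warning; an empty beat list renders a valid baseline-only signal;
  zero-variance heart-rate targets make the normalizer error rather than
  divide by zero.
* Heart rates outside 20–250 bpm are treated as undefined rather than
  reported.

## Problem sizes used by the tests

The suite exercises full overnight scale only where the property demands it
(ten simulated 7-hour nights for the availability statistic) and otherwise
uses 1–30 minute sessions, which already contain hundreds of beats. The
CNN's held-out-accuracy property runs on an 18-subject cohort of 30-minute
sessions (12 training / 6 held-out) — a deliberate desk-scale reduction of
the 24-subject overnight trial design that keeps the subject-wise split
structure intact. These sizes are the package's own trade-off between
statistical resolution and a test suite that runs in minutes.

## Known limitations

* The algorithmic core processes windows independently; a beat straddling a
  window boundary can be missed, which mildly biases very short sessions.
* The causal band-pass delays J positions by a sample or two; irrelevant
  for per-window rates, but do not use the detected indices for
  beat-to-beat timing against an external clock without accounting for it.
* The CNN is trained and evaluated on simulator output here; transferring
  the trained weights to real belts requires real training data.
* `detect_saturation_spans` only finds rail-touching artifacts; large
  motion that stays inside the ADC range passes the repair stage and must
  be caught by the window-exclusion fraction or not at all.
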