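---
title: "Localizing heart sounds in lung-sound recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing heart sounds in lung-sound recordings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartloc)
```

## The problem

Electronic auscultation of the lungs is corrupted by the heart: the
first and second heart sounds (S1, S2) — and, in pathological hearts,
the gallop sounds S3 and S4 — overlap the lung sound (LS) in time and,
below roughly 150 Hz, in frequency as well. Most heart-sound reduction
schemes need to know *where* the heart sounds are before they can remove
them. `heartloc` implements a localization algorithm for exactly that
preprocessing step: given a mono auscultation recording (16-bit PCM WAV,
nominally 8 kHz), it returns the sample intervals occupied by
heart-sound components. It does not classify which component is which,
and it does not remove anything.

## The algorithm

The pipeline in `localize_hs()` is:

1. **Amplitude normalization.** The waveform is divided by its absolute
   maximum \(M\), so \(y_{norm}(n) = y(n)/M \in [-1, 1]\). This removes
   instrument-gain and subject-to-subject amplitude differences. (A
   degenerate all-zero record has no scale; the pipeline returns an
   empty segment set for it.)
2. **Cardiac-band enhancement.** A 10th-order Butterworth low-pass at
   150 Hz attenuates the broadband LS and murmur energy above the band
   where S1–S4 live (roughly 20–150 Hz).
3. **Hilbert envelope.** The analytic signal \(x + i\,H\{x\}\) is
   computed by the DFT construction — keep DC, double positive
   frequencies, zero negative ones, and keep the Nyquist bin when the
   record length is even. The envelope is its magnitude
   \(E_H(n) = \sqrt{x^2 + H\{x\}^2}\), which bounds \(|x(n)|\) pointwise
   and equals the amplitude of a narrow-band tone.
4. **Envelope smoothing.** A 5th-order Butterworth low-pass with cutoff
   \(f_c \in [7, 25]\) Hz (default 15 Hz) removes the fast LS ripple so
   that one acoustic event maps to one envelope bump.
5. **Peak formation.** Extrema of the smoothed envelope are sign changes
   of the first difference; each maximum with its two flanking minima is
   a candidate event. Record endpoints serve as boundary minima when an
   event touches the edge.
6. **Heron-area scoring.** Each candidate is the scalene triangle
   through its three extrema in (time, envelope) coordinates; its area
   comes from Heron's two-step formula — semiperimeter
   \(h = (u+v+w)/2\), then \(\sqrt{h(h-u)(h-v)(h-w)}\). Heart-sound
   bumps are tall and wide, so their triangles are large.
7. **Adaptive thresholding and boundaries.** A peak is kept iff its area
   exceeds `threshold_scale` times the population variance of the area
   vector. Kept peaks span their flanking minima; adjacent kept peaks
   sharing a minimum merge into one segment.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `hs_filter_cutoff_hz` | 150 | Hz | upper edge of the cardiac band |
| `hs_filter_order` | 10 | — | roll-off steepness of the enhancement filter |
| `smooth_cutoff_hz` | 15 | Hz | envelope smoothing; lower = wider detected events |
| `smooth_order` | 5 | — | smoother roll-off |
| `threshold_scale` | 1.0 | — | multiplier on the area-vector variance |
| `filter_mode` | `"zerophase"` | — | forward–backward vs single causal pass |
| `x_scale` | `1/rate` (seconds) | s/sample | horizontal units of the peak triangles |
| `y_scale` | 1 | — | vertical units of the peak triangles |

The smoothing cutoff is the parameter that matters most: it trades the
width of detected events (low \(f_c\)) against their temporal precision
(high \(f_c\)); the working range 7–25 Hz brackets the ~1–3 Hz event
rate of cardiac sounds well below the cardiac-band content.

## Numerical choices

* **"Zero-phase" filtering.** The source method calls for a "Butterworth
  FIR" filter — a contradiction, since Butterworth designs are IIR. We
  use a Butterworth IIR applied forward–backward (`filter_mode =
  "zerophase"`), which squares the magnitude response (−6 dB rather
  than −3 dB at the cutoff) and cancels group delay. Localization is a
  *timing* task; an uncompensated 10th-order IIR at 150 Hz would shift
  every boundary by several milliseconds. A single causal pass remains
  available as `filter_mode = "single"`.
* **Filter realization.** Filters are designed as cascaded biquads
  (second-order sections); transfer-function polynomials of order 5–10
  at normalized cutoffs as low as 15 Hz / 8 kHz are numerically fragile.
  Each section is seeded with its constant-input steady state, and
  zero-phase application uses odd (point-reflected) end extension of
  length three times the filter order, so constant signals pass exactly
  and startup transients are confined to the record edges.
* **Threshold units.** Triangle areas are bilinear in the axis scales,
  but the variance of the area vector is *quadratic* in them, so the
  select-if-area-exceeds-variance rule changes behaviour with the units
  of the time axis. With sample-index units at 8 kHz, areas are
  \(O(10^2)\) and the variance exceeds every area — the rule would
  select nothing. Areas are therefore computed in **seconds** ×
  normalized-envelope units by default (`x_scale = 1/rate`), where areas
  are \(O(10^{-2}\!-\!10^{-1})\) and the rule behaves as described.
  Both scales are exposed.
* **Degeneracies.** A negative Heron radicand (floating noise on
  near-collinear triangles) clamps to zero; collinear peak triangles are
  flagged, not errors; negative smoothing ringing clamps the envelope at
  zero; ties on plateau extrema resolve to the plateau's first sample.
* **The operating point, honestly.** At the default
  `threshold_scale = 1` the variance threshold is *permissive*: on the
  synthetic mixtures below it keeps nearly all candidate peaks, which
  preserves the zero-false-negative behaviour that is the method's
  headline claim, at the price of a high false-positive rate (segments
  cover most of the record; the source publication reports FPR of
  1–16 % on its own recordings instead). Raising `threshold_scale` (or
  switching the rule to a standard-deviation scale) makes the detector
  discriminating on low-flow mixtures but measurably breaks the
  zero-FNR property at medium/high flow in our synthetic world, because
  the heart- and lung-peak area populations genuinely overlap there. We
  keep the permissive default; users who care about FPR should sweep
  `threshold_scale` on their own data.

## The synthetic-data generator

No recordings are distributed with the package, so `synth_mixture()`
builds test material from first principles:

* **Heart sounds** are Hann-windowed tone bursts placed once per 0.8 s
  cycle: S1 (60 Hz, 120 ms, amplitude 1.0) and S2 (85 Hz, 90 ms, 0.75)
  for a "normal" heart; S3 (35 Hz, 70 ms, 0.35) after S2, S4 (40 Hz,
  60 ms, 0.30) before S1, plus a 200–600 Hz systolic murmur burst, for
  an "abnormal" one. Phases and ±10 % amplitude jitter are drawn per
  instance. Ground truth labels each instance's nominal support
  `[onset, onset + duration)`.
* **Lung sounds** are Gaussian noise shaped to the respiratory band
  (high-pass 20 Hz; gentle 2nd-order roll-off above 200 Hz so most
  energy sits below 200 Hz while content extends toward 1600 Hz),
  amplitude-modulated by a 4 s breathing cycle; the "abnormal" variant
  adds an expiration-gated 400 Hz wheeze.
* **Convolutive mixing** draws two random 4-tap FIR filters with
  standard-normal taps: the heart-path taps are rescaled to unit norm,
  the lung-path taps to a norm drawn uniformly from the flow stratum's
  range (e.g. 0.10–0.80 low, 0.81–3.10 medium, > 3.10 high for the
  normal–normal mixture type; open-ended "high" cells draw from
  \((L, 2L]\)). Both sources are peak-normalized before mixing — the
  convention of amplitude-normalized WAV sources.

What the generator does **not** emulate: physiological heart-rate and
breath variability, recording-chain coloration beyond 4-tap FIR,
crackles/squawks, sensor artifacts. A green test on this material
establishes algorithmic correctness under the stated model, not
clinical performance.

Two consequences of the stated world are worth knowing. First, labels
cover each component's *nominal* support, including the Hann onset ramp
where the component is far below the lung-sound floor; detected
boundaries (flanking envelope minima) routinely start 10–30 ms inside
that inaudible ramp for the weak S3/S4, so strict per-sample recall of
100.000 % is not achievable — a human-annotated reference would not
include those samples. Second, standard-normal mixing taps occasionally
nearly null the 35–60 Hz band, burying a component outright (≈0.06 % of
injected components in our acceptance grid). Both effects are visible
as small, documented residuals in the acceptance suite rather than
hidden by loosened tolerances. Likewise, the classic trade-off —
false negatives rising and false positives falling as the smoothing
cutoff increases — expresses itself cleanly only at a discriminating
threshold; at the permissive default the FPR is saturated and wiggles
non-monotonically with the cutoff on some mixtures.

## Evaluation metrics

`evaluate_segments()` scores per sample by default: FNR
\(= 100\,FN/(FN+TP)\), FPR \(= 100\,FP/(FP+TN)\), ACC
\(= 100\,(TP+TN)/n\), DER \(= 100\,(FP+FN)/n\), so ACC + DER = 100
identically. Ratios with empty denominators are `NA`, never silently 0.
An event-level mode (`mode = "event"`, CLI `--per-event`) counts a true
segment as detected if any predicted segment overlaps it; event mode
has no true negatives, so only FNR (and the raw counts) are reported
there.

## A worked run

```{r example}
mix <- synth_mixture(flow = "low", mixture_type = "normal-normal",
                     duration = 6, seed = 7)
segs <- localize_hs(mix$signal)
head(as.data.frame(segs))
evaluate_segments(segs, mix$truth)
```

Every injected S1/S2 is intersected (FNR 0 %); the permissive default
threshold makes the segments wide, which the FPR reflects.

## Known limitations

* The FPR at the default operating point is far above the source
  publication's printed values on its (undeposited) recordings; see
  "The operating point, honestly" above.
* WAV support is deliberately minimal: RIFF/PCM16 only, first channel
  of multi-channel files, no resampling or compressed formats.
* Segments are localized, not labelled: the package never says which
  segment is S1 versus S2/S3/S4.
* The discrete Hilbert envelope is exact for finite records but edge
  effects within roughly one smoothing time constant of the record ends
  are unavoidable; records shorter than three smoothing time constants
  are rejected.
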