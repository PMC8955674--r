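---
title: "Methods: murine HRV extraction, pain scoring, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: murine HRV extraction, pain scoring, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murihrv)
```

# Scope and model

`murihrv` turns single-channel mouse ECG into heart rate variability
(HRV) metrics and relates them to a four-category welfare score. The
underlying physiological model is standard: the sinoatrial node is
modulated by both autonomic branches; parasympathetic (vagal) influence
acts beat-to-beat and dominates the high-frequency band and the
successive-difference statistics (RMSSD, pNN5), while the low-frequency
band mixes sympathetic and parasympathetic drive. In mice the relevant
time scales sit an order of magnitude above the human ones: resting R-R
intervals of roughly 100–150 ms, LF defined as 0.1–1.0 Hz and HF as
1.0–4 Hz.

The processing chain is: bandpass conditioning → R-peak detection → R-R
interval (RRI) formation → 3-minute window selection → artifact
screening → time-domain metrics on the interval series and
frequency-domain metrics on a spline-interpolated 10 Hz tachogram via
Welch's method.

# The synthetic generator and what it stands in for

Real murine telemetry for this kind of study is rarely shareable, so the
package ships a generator that every downstream stage is validated
against.

**RR level.** `generate_rri()` uses an interval-sampling approximation
of integral pulse frequency modulation (IPFM): the instantaneous
interval is

RR(t) = mean_rr + lf_amp·sin(2π·lf_freq·t) + hf_amp·sin(2π·hf_freq·t),

and the i-th interval equals RR evaluated at the (i−1)-th beat time plus
independent Gaussian jitter. We deliberately sample RR(t) per beat
rather than integrating to threshold: it is exactly invertible for
testing, and at the modulation depths used here (a few ms on a ~100 ms
carrier) the two formulations are indistinguishable. Jitter draws are
truncated at ±4 sd, which together with the configuration invariant
`lf_amp + hf_amp + 4·jitter_sd < mean_rr` guarantees strictly positive
intervals.

Two useful closed forms follow from this model. A sinusoid of amplitude
A at frequency f, sampled approximately every T = mean_rr, contributes
2A²sin²(πfT) to the mean squared successive difference, and white jitter
of sd σ contributes 2σ², so

E[RMSSD²] ≈ 2σ² + Σ_b 2A_b² sin²(π f_b T).

`expected_rmssd()` and `jitter_for_rmssd()` implement this pair; the
test suite checks the formula against simulation and uses the inverse to
set jitter for a target RMSSD.

**Waveform level.** `generate_ecg()` renders one five-Gaussian PQRST
template per beat (R: 1 mV, 5 ms full-width-at-half-maximum; widths are
FWHM, converted internally to Gaussian sd), plus single-tone baseline
wander (0.3 Hz by default, respiration scale) and white Gaussian noise.
A lead-in of one template half-span keeps the first beat fully inside
the record; a beat cut off at the edge otherwise produces a large
filtering transient that can poison detector threshold initialization.
The default sampling rate is 2 kHz — ample for a 50 Hz analysis band and
±0.5 ms timing — with telemetry-grade 32 kHz available via
configuration and handled by `decimate_ecg()`.

**What the generator does not emulate**: ectopic beats, electrode
motion artifacts, powerline and EMG interference, non-sinusoidal or
nonstationary autonomic modulation, circadian drift, and between-animal
heterogeneity (see "Cohort simulation" below). Passing tests therefore
demonstrate correctness of the algorithms under clean, stationary,
known-truth conditions — not robustness to every failure mode of real
telemetry.

# Conditioning

The bandpass is a 3rd-order Butterworth, 0.5–50 Hz, applied
forward-backward (`filtfilt`), giving zero phase and an effective
6th-order magnitude response. Zero-phase application matters because
R-peak *timing* feeds every HRV metric; a causal filter would shift
peaks by a frequency-dependent group delay. Edge transients are
suppressed by odd-reflection padding sized at three time constants of
the slowest pole (3·fs/low_cut samples), after which a DC step is
attenuated below 10⁻⁴ of its amplitude.

A note on the passband: 0.5–50 Hz is low for mouse QRS complexes, whose
~5 ms width puts most of their energy above 50 Hz. The filter therefore
substantially smooths the QRS. Detection still performs at
sensitivity/PPV ≥ 0.99 under the tested noise levels, but the smoothing
is the reason several detector safeguards below exist. The passband is
configurable via `filter_spec()` for users who prefer a wider QRS band.

Decimation uses a zero-phase Butterworth anti-alias lowpass (order 5 per
pass, cutoff 0.8× target Nyquist) followed by natural-spline regridding,
supporting arbitrary rate ratios with >40 dB alias suppression. This is
implemented in-package because it must be zero-phase — resampling that
delays the waveform would bias every interval.

# R-peak detection

`detect_rpeaks()` follows the Pan–Tompkins chain with constants rescaled
to mouse physiology:

| constant | value | rationale |
|---|---|---|
| integration window | 12 ms | ≈ rodent QRS width (human original: 150 ms) |
| refractory | 30 ms | guards the ~2000 bpm upper bound of mouse HR |
| threshold position | 0.25 between noise/signal levels | classic value |
| level update EMA | 0.125 | classic value |
| search-back trigger | 1.66 × running mean RR | classic value |
| search-back threshold | 0.5 × detection threshold | classic value |
| refinement window | ±10 ms | restores ms timing after integration |

Thresholds are initialized from the first 2 s (signal level = 0.7 × max
of the integrated signal, noise level = 0.5 × mean) and updated as
exponential moving averages. All thresholds are ratios of running
levels, so detection is invariant to amplitude scaling.

Three design choices deserve explanation:

* **Delay compensation before refinement.** The causal moving-window
  integrator shifts its peak roughly half the integration window after
  the R wave. Refinement therefore searches the filtered ECG around the
  candidate minus that lag; ties on plateaus resolve to the earliest
  sample. Without compensation the ±10 ms refinement window can miss
  the true R entirely.
* **Polarity.** The derivative–squaring–integration stages are exactly
  polarity-invariant, so running the detector on the negated signal
  cannot change the candidate set. Electrode polarity is instead
  resolved at refinement: peaks are refined against both the signal and
  its negation and the orientation with the larger mean refined
  amplitude wins (the R deflection dominates in either orientation).
* **Rhythm-plausibility gate.** Because the 0.5–50 Hz filter smooths
  QRS energy into the same scale as integrated noise, no per-peak
  threshold cleanly rejects detections on a beat-free record: adaptive
  signal/noise levels equilibrate inside the noise-maximum distribution
  and accept a steady trickle of false peaks. Cardiac rhythm, however,
  is quasi-periodic: on synthetic mouse ECG the robust coefficient of
  variation of detected R-R intervals (IQR/median) stays below ~0.1 up
  to heavy noise, while on beat-free noise it exceeds 0.7. If the
  robust CV exceeds `max_rhythm_cv` (default 0.4) the record is
  declared to contain no reliable rhythm and an empty peak set is
  returned. The corollary is deliberate: a record so corrupted that its
  detections are arrhythmic at CV > 0.4 is reported as unanalyzable
  rather than contributing millisecond-precision metrics computed from
  garbage. Set `max_rhythm_cv = Inf` to disable.

# Interval processing

`peaks_to_rri()` stamps each interval with the time of the beat ending
it; this convention propagates to windowing (an interval belongs to the
half-open window `[t0, t0 + 180 s)` iff its ending beat does) and to the
tachogram knots. The default window is the centered 3 minutes of a
5-minute recording: recordings begin and end with handling stress, and
centering avoids both transients. Start/end placements are available.

Artifact screening flags intervals outside 50–300 ms or jumping more
than 30% from the previous retained interval. The defaults are
permissive and screening can be disabled, because the analysis this
package models reports no artifact handling; the screen exists so users
with real telemetry are not defenseless against dropped or doubled
beats. Excluded intervals contribute to no metric, and
successive-difference metrics use only adjacent retained pairs with no
exclusion between them — a dropped beat costs its two pairs rather than
injecting a spurious 2× interval difference. The bounds screen is
pointwise and commutes with windowing; the relative-jump rule is
sequential and does not, which is why the package applies screening
after windowing.

# Time-domain metrics

Mean RRI is the arithmetic mean of retained intervals. RMSSD divides by
the number of pairs (N−1 for an unscreened series), not N. pNN5 uses a
strict `> 5 ms` comparison on the absolute successive difference;
comparing the signed difference would count only accelerations and
contradict the universal pNNx convention, but a signed mode is available
(`absolute = FALSE`). All three are verified against an independent
double-loop reference on randomized series to 10⁻⁹ relative tolerance.

# Frequency-domain metrics

The tachogram is a natural cubic spline through (ending-beat time,
interval) knots, evaluated on a uniform 10 Hz grid from the first knot
to the last — interpolation only, no extrapolation, minimum four knots.
10 Hz comfortably oversamples the 4 Hz HF edge.

Welch's estimator averages modified periodograms over 512-sample
segments (51.2 s at 10 Hz → ~0.02 Hz resolution, resolving the 0.1 Hz
LF edge; a 3-minute tachogram yields 6 half-overlapping segments) with a
Hann window and per-segment mean removal. The one-sided PSD is scaled by
1/(fs·Σw²) so that its integral over [0, Nyquist] equals the variance of
the detrended signal; the suite checks this Parseval property on white
noise and checks tone power recovery (a²/2) on sinusoids. Mean
detrending also makes band powers invariant to the tachogram's mean
level.

Band powers integrate the piecewise-linear PSD by trapezoid with
pro-rata contributions at band edges, so LF = [0.1, 1.0) and
HF = [1.0, 4.0] partition cleanly: the shared 1.0 Hz edge is owned by HF
by convention, and edge splitting makes the choice numerically
negligible. Total power is reported over 0.1–4 Hz, the union of the
defined bands — "total" is otherwise ambiguous, and the sub-0.1 Hz
region of a 3-minute recording holds at most one or two cycles. LF/HF
is flagged `NA` when HF power is zero.

# Pain rubric

Four categories score 0/1 each; the total spans 0 (normal) to 4 (most
painful). Choices the source material left ambiguous:

* The temperature criterion is implemented as *outside* the 35.8–37.4 °C
  normal range in either direction. Rubric tables of this kind
  sometimes say "above normal temperature", but tumor burden depresses
  body temperature in practice, and a hypothermic animal is not a
  healthy one. An `temp_rule = "above"` switch restores the
  hyperthermia-only reading.
* The activity criterion scores 1 when any gap between consecutive
  movement/grooming events strictly exceeds 30 s, with the gaps from
  observation start to the first event and from the last event to the
  end included — an animal inactive for the first 40 s of the
  observation is inactive.
* A first observation (no previous weight) evaluates temperature and
  diarrhea only.

# Group statistics

Mann–Whitney uses the exact null distribution when the smaller group has
≤ 8 observations and the pooled data are tie-free — exactly the regime
of 4–8-animal designs — and the tie-corrected normal approximation with
continuity correction otherwise. Kruskal–Wallis applies the standard
tie-corrected H against χ²(k−1); the all-values-identical degenerate
case returns H = 0, p = 1 rather than an error (the tie-correction
denominator vanishes there). Post hoc comparisons after Kruskal–Wallis
are pairwise Mann–Whitney tests with Bonferroni adjustment over the
number of pairs — the adjustment method is fixed by the design being
modeled, and Mann–Whitney is the consistent nonparametric pairwise
choice. All tests are two-sided. Summaries are mean ± SEM with the n−1
variance; SEM for n = 1 is reported as 0 with a warning.

# Cohort simulation

`simulate_cohort()` builds study-like two-group cohorts at the
RR-interval level: 5 healthy-profile subjects (mean RR 135.87 ms, RMSSD
11.13 ms) versus 8 tumor-profile subjects (mean RR 98.69 ms, RMSSD
3.60 ms), each subject generated with its own seed, RMSSD realized via
`jitter_for_rmssd()` on top of mild LF/HF modulation. Subjects within a
group share the group-level configuration and differ only through
generator randomness; the simulation reproduces group *means* and the
direction of the group difference, not between-animal spread. This is a
deliberate scaled-down design: with realistic 13-subject cohorts it
verifies that the full metric chain plus Mann–Whitney recovers the
expected separation on every time-domain metric, and the test suite
requires that separation in at least 95% of replicate studies.
Consequently the simulated p-values should not be read as a power
analysis for real cohorts, where between-animal variance is substantial.

# Numerical choices and problem sizes

* Zero-phase IIR filtering accumulates rounding error through recursion
  with poles near the unit circle; linearity holds to ~10⁻⁷ relative,
  not machine precision, and the tests assert it at 10⁻⁶.
* Plateau ties in peak refinement resolve to the earliest sample;
  refractory violations after refinement keep the stronger peak.
* The generator's duration loop uses a 1 ns tolerance so that an exact
  integer number of beats does not gain a spurious extra interval to
  float drift.
* Validation sizes were chosen to exercise every code path while
  keeping the default suite fast: 300 randomized series for metric
  oracle equivalence in the unit tests and 1000 in the acceptance
  tests (lengths 2–2000), 20 five-minute recordings at 10 dB SNR for
  detector performance, 100 replicate 13-subject cohort studies for
  group separation, and 2000 null simulations for Mann–Whitney
  calibration.

# Known limitations

* The detector is tuned for, and validated on, mouse-scale rhythms; the
  constants are exposed but no human/rat presets ship.
* The rhythm gate trades extreme-noise sensitivity for specificity: a
  record whose detections are arrhythmic beyond CV 0.4 yields zero
  beats rather than partial results.
* No nonlinear HRV indices (Poincaré SD1/SD2, entropies, DFA) — the
  time- and frequency-domain set models the analysis this package
  targets; nonlinear indices are a natural extension.
* File I/O covers the package's documented text formats only; vendor
  acquisition formats are out of scope.
* No repeated-measures modeling: each timepoint is tested
  independently, matching the design being reproduced.
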