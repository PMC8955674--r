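# murihrv

Heart rate variability (HRV) analysis for single-channel mouse ECG.

Autonomic nervous system activity — the balance of sympathetic and
parasympathetic drive — leaves a measurable signature in the beat-to-beat
fluctuation of the R-R interval (RRI). In mice, depressed HRV accompanies
stress, disease burden and pain, so HRV extracted from short telemetry
recordings can serve as an objective welfare indicator alongside
observational scoring. `murihrv` implements the full chain from raw
voltage samples to group-level statistics, with every constant scaled to
murine physiology (resting RRI ~100–150 ms, HRV modulation bands an
order of magnitude above the human ones), plus a synthetic mouse-ECG
generator with known ground truth so the whole chain is testable without
animal data.

## What it computes

For each recording, on a 3-minute analysis window:

* **Time domain** — mean RRI; RMSSD
  = √( Σᵢ (RRᵢ₊₁ − RRᵢ)² / (N−1) ), a vagal-tone index; pNN5
  = 100 · #{ |RRᵢ₊₁ − RRᵢ| > 5 ms } / (N−1), the rodent analogue of pNN50.
* **Frequency domain** — the RRI series is resampled to a uniform 10 Hz
  tachogram by natural cubic spline and its power spectrum estimated by
  Welch's method; LF power (0.1–1.0 Hz), HF power (1.0–4 Hz), their
  ratio LF/HF, and total power (0.1–4 Hz), all in ms².
* **R-peak detection** — a Pan–Tompkins style detector (zero-phase
  0.5–50 Hz Butterworth conditioning, five-point derivative, squaring,
  12-ms moving-window integration, adaptive dual thresholds with
  search-back, 30-ms refractory), with each detection refined to the
  local maximum of the filtered ECG so that RR intervals carry
  millisecond timing.
* **Pain rubric** — a four-category 0–4 welfare score (physiological
  signs, posture, appearance, activity), each category scored 0/1 from
  observation logs: >10% body-weight change, temperature outside
  35.8–37.4 °C or diarrhea; hunched posture; rough coat / pinched face /
  distended abdomen / reluctance to move; any inactivity gap longer than
  30 s in a 5-min observation.
* **Group statistics** — mean ± SEM summaries, Mann–Whitney (exact for
  the small group sizes typical of these designs), Kruskal–Wallis with
  Bonferroni-adjusted pairwise post hocs.

## Worked example

Simulate a 5-minute mouse ECG with known beat times, run the detector,
and compute HRV:

```r
library(murihrv)

cfg <- rr_synth_config(mean_rr = 120, lf_amp = 3, lf_freq = 0.4,
                       hf_amp = 4, hf_freq = 2.5, jitter_sd = 3,
                       duration = 300, seed = 42)
g <- generate_rri(cfg)
e <- generate_ecg(g$series, ecg_synth_config(noise_sd = 0.05, seed = 42))
e$record
#> <ecg_record> 600392 samples @ 2000 Hz (300.20 s)

peaks <- detect_rpeaks(bandpass(e$record))
peaks
#> <rpeak_set> 2504 peaks, mean RR 119.9 ms

m <- match_to_truth(peaks, e$truth, tol = 5)
sprintf("sensitivity %.4f, PPV %.4f, timing MAE %.2f ms",
        m$sensitivity, m$ppv, mean(abs(m$timing_errors)))
#> "sensitivity 1.0000, PPV 1.0000, timing MAE 0.18 ms"

hrv_from_rri(peaks_to_rri(peaks))
#> $mean_rri    119.9      # ms — recovers the configured 120 ms
#> $rmssd       6.298      # ms — jitter + fast HF modulation
#> $pnn5        45.93      # % of successive differences > 5 ms
#> $lf_power    6.41       # ms², 0.1–1.0 Hz (0.4 Hz tone configured)
#> $hf_power    12.88      # ms², 1.0–4 Hz (2.5 Hz tone configured)
#> $lf_hf       0.4976
#> $total_power 19.29      # ms²
#> $n_beats     1502       # beats in the 3-min centered window
#> $n_excluded  0
```

Every detected beat matched ground truth within 5 ms, and the recovered
mean RRI is within 0.1% of the generator setting. The pain rubric works
from plain observations:

```r
obs <- pain_observation(body_weight = 31, prev_body_weight = 28,
                        body_temp = 35.5, diarrhea = TRUE,
                        hunched_posture = TRUE,
                        activity_event_times = c(0, 120, 290))
total_pain_score(obs)
#> <pain_score> total 3/4 (physiological 1, posture 1, appearance 0, activity 1)
```

(10.7% weight gain, below-range temperature and diarrhea each flag the
physiological category once; the 120-s inactivity gaps flag activity; no
appearance signs were observed.)

Whole cohorts run through `simulate_cohort()` → `run_study()`, which
returns per-subject metric rows, group mean ± SEM summaries, and the
nonparametric tests.

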