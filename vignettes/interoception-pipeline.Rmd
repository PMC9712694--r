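---
title: "Cardiorespiratory and fNIRS analysis of interoceptive tasks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiorespiratory and fNIRS analysis of interoceptive tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`interopipe` analyses experiments in which subjects rest, silently count
their heartbeats, and breathe at paced rates while ECG, a respiratory belt
(both 250 Hz), and 23 frontal fNIRS channels (50 Hz, 760/840 nm) are
recorded. This vignette explains each model and procedure, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## Signal models

### Beat detection and the IBI series

The ECG is band-passed (Butterworth 0.5–45 Hz, order 4) and R-peaks are
found in two passes: adaptive-threshold local maxima with a 250 ms
refractory period propose beats; the median beat waveform (±100 ms) is then
correlated against the whole trace and events are re-picked wherever the
normalised correlation exceeds 0.6. Because band-limited noise can exceed a
pure correlation threshold on near-zero-energy stretches, detected events
must also reach a fraction of the provisional-beat amplitude (40% for ECG,
whose R deflection towers over baseline; 15% for breathing, where 2-s
smoothing leaves the fastest paced rate at roughly a quarter of the
slow-breathing amplitude). Inhalation peaks use the same scheme on the 2-s
moving-mean-smoothed belt signal with a 1.5 s refractory period.

All filtering in the package is zero-phase (forward–backward). The lag
quantities downstream — the ~10 s cardiorespiratory lag, per-channel
breathing-response latencies — would be biased by a causal filter's group
delay; the effective doubling of filter order is an acceptable price.

Ectopic intervals are flagged where the absolute IBI derivative has a local
maximum exceeding `median + 4·MAD` (unscaled MAD). An unqualified
local-maximum rule would flag roughly every other interval, so a robust
amplitude criterion is required; 4·MAD sits far outside the derivative
range that respiratory sinus arrhythmia at physiological depth produces
(verified by simulation: ≤5% false-flag rate over 100 modulated records).
Flagged intervals are replaced by natural-cubic-spline interpolation over
their unflagged neighbours and event times are rebuilt cumulatively —
deterministic interpolation replaces interactive manual editing, and the
flags are retained so a human can still review what was changed.

### Rates and spectra

The instantaneous rate is `1/IBI`, assigned at the event closing each
interval and cubic-spline-interpolated to a uniform 4 Hz grid (Nyquist
2 Hz, comfortably above the 0–0.5 Hz band of interest). Assigning at the
closing event delays the rate series by about half an interval relative to
the modulation that generated it; the recovered coupling lag therefore
reads ~0.4 s above the injected value, within the package's stated ±0.5 s
recovery band.

HRV spectra are Burg autoregressive PSDs of order 16 — the standard HRV
recommendation — computed on the mean-removed IBI series (the interval
series, not the rate series, matching reference HRV practice; at these
modulation depths the two differ negligibly). The spectrum is evaluated on
1024 points over 0–2 Hz (bin ≈ 0.002 Hz, finer than the dispersion of
group-level dominant-frequency estimates), and the dominant frequency is
the PSD maximum within 0–0.5 Hz, ties broken toward the lower frequency; if
the global spectral maximum lies outside the band the value is flagged
low-confidence.

### Cardiorespiratory coupling

The coupling statistic is the Spearman rank correlation between the
breathing waveform and the 2-s-smoothed heart-rate series, evaluated at
every lag on the ±30 s grid in steps of the 0.25 s resampling period, on
the shrinking overlap without padding. The reported value is the signed
coefficient of maximum magnitude and its lag. Sign convention: positive lag
means heart-rate changes *follow* breathing changes, so breathing-driven
RSA yields a positive lag. A circular-shift surrogate null (uniform shifts
of at least 30 s) provides the 95th-percentile chance level of `|ρ_max|`.
Whether the raw breathing waveform or the breathing-rate series should be
correlated is open in principle; the waveform is used, as it is the signal
the belt records.

### fNIRS

Intensities become optical densities via `−log10(I/mean(I))`; the 2×2
modified Beer–Lambert system at 760/840 nm is solved per sample for
(ΔHbO, ΔHbR) using Gratzer/Prahl extinction coefficients, a 3.5 cm
source–detector separation and DPF 6. The wavelength pair, DPF and
extinction table only rescale the concentrations; every downstream result
is rank-based (Spearman) and cannot depend on that choice. Only ΔHbO is
analysed; ΔHbR is retained in the container.

Connectivity is the pairwise Spearman matrix over a segment (≥30 s), with
each channel summarised by the median of its 22 off-diagonal entries.

The breathing-locked component is extracted by PCA on the z-scored matrix
of 23 HbO channels plus the breathing signal as a 24th column
(correlation-matrix PCA, since channels and breathing are in
incommensurable units). Each component score is correlated with breathing
by max-|ρ| Spearman over ±30 s lags; components exceeding 0.6 are
back-projected onto the 23 HbO loadings only — reconstructing the breathing
column itself would be circular — and summed. Two guards follow from that
inclusion decision: a component loading almost exclusively on the breathing
column (HbO-loading norm below 0.5) is excluded, because it correlates with
breathing by construction while carrying no hemodynamic content; and when
nothing passes, the result is an explicitly flagged empty response, not an
error. A channels-only PCA mode (`include_breathing_column = FALSE`) is
also provided. For speed, the lag-correlation scans run on 10 Hz decimated
copies (both signals are band-limited far below that Nyquist) with a 0.5 s
selection grid and a 0.1 s grid for per-channel response lags.

### Task statistics

Counting accuracy is `1 − (beats_ECG − beats_counted)/beats_ECG`, exactly
as defined — without an absolute value, so over-counting scores above 1; a
symmetric `absolute = TRUE` variant exists but is not the default. Subject
scores average the trials. Transition analyses cut per-trial epochs around
event onsets on a common relative grid, average trials per subject, then
z-score the averaged window (mean 0, sd 1 over the window; constant epochs
become zeros with a `degenerate` flag rather than NaN). For a step-like
response with equal half-windows this forces the pre/post means to be exact
negatives — the ± structure that group transition tables show.

The paired Wilcoxon test uses the tie-corrected normal approximation with a
signed z. Its Monte-Carlo correction randomises signs of the paired
differences — the exchangeability structure of a paired design — and
recomputes the Wilcoxon p for each of 10,000 permutations; since the ranks
of |d| are flip-invariant, each permutation's p follows from its
positive-rank sum, which lets the whole null distribution be computed by
one matrix product. `p_mc = (1 + #{p_perm ≤ p_obs})/(n_perm + 1)`; the
add-one estimator avoids zero p-values. The Friedman statistic carries the
standard tie correction; Spearman p uses
`t = ρ√((n−2)/(1−ρ²))` with n−2 df; the channel-wise Bonferroni threshold
is α/23.

Group dispersion is the *unscaled* median absolute deviation — a
descriptive companion to the median, not a normal-consistent scale
estimate.

## The synthetic-data generator

The generator emulates the study design with known ground truth:

* **Protocol** — 180 s rest; six counting blocks with uniform durations in
  [30, 60] s, each followed by a 15 s report window (report durations are
  not constrained by the protocol description; 15 s keeps the adjacent
  "not counting" windows long enough for transition contrasts); 60 s rest;
  then the paced programme in which each staircase
  (0.1–0.2–0.4–0.2–0.1 Hz and 0.15–0.3–0.4–0.3–0.15 Hz, 50 s per step)
  appears twice, with 30 s rests inside a pair and 60 s between pairs, so
  every rate occurs exactly four times.
* **Breathing** — a raised cosine per cycle driven by a phase accumulator
  (plethysmography-like, phase-continuous across paced transitions, since
  real subjects do not produce waveform discontinuities at step changes);
  free breathing at 0.25 Hz with slow seeded jitter.
* **Heartbeats** — integral pulse frequency modulation: beats fire when the
  integral of
  `mean_hr·(1 + rsa_gain·b(t − rsa_lag_s) + lf_gain·sin(2π·0.1·t))`
  crosses successive integers, integrated on the 4 ms sample grid with
  linear interpolation of crossing times (accurate to well under 1 ms).
  Defaults: 1.2 Hz mean rate, RSA gain 0.15, Mayer gain 0.05, RSA lag 10 s
  — the lag chosen to mirror the ~10 s breathing-to-heart-rate lag the
  coupling analysis is designed to detect.
* **ECG** — a fixed QRS-like template (unit R amplitude, ~80 ms wide) at
  each beat plus white noise (default SD 5% of R).
* **fNIRS** — each channel mixes a shared band-limited 0.05–0.15 Hz slow
  oscillation with seeded per-channel weights, the breathing waveform at a
  per-channel gain and lag, a smooth cardiac pulse train, and white noise;
  the forward optical densities are computed from the same extinction
  table the analysis inverts, with ΔHbR fixed at −0.3·ΔHbO (HbR exists
  only to make the two-wavelength inversion non-trivial).

Ground truth (beat times, breath peaks, injected per-channel components)
travels in a separate `truth` structure that no analysis stage reads, so
recovery tests cannot leak.

### What the generator does not emulate

No motion artifacts, electrode noise bursts, T/P waves, stroke-volume
effects, scalp-coupling variation, or genuine neural task responses.
Passing recovery tests therefore demonstrates that the pipeline is
*internally correct* — it recovers what was injected, at the stated noise
levels — not that it is robust to every artifact class of real recordings.

### Two capacity limits found by construction

Two properties of the extraction methods surfaced while validating the
generator and are worth knowing when interpreting real data:

* **Lag dispersion vs the 0.6 rule.** Delayed copies of a breathing
  waveform span a subspace whose dimension grows with the lag spread.
  When the per-channel fNIRS lags spread over several seconds, the
  breathing variance splits across many principal components whose
  individual correlations with breathing fall below the fixed 0.6
  selection threshold, and the reconstruction truncates genuine breathing
  content (measured: minimum per-channel recovery ρ ≈ 0.78 at a 6 s
  spread, ≈ 0.95 at a 1 s spread). The generator's default lag vector
  spans 4.5–5.5 s — a near-synchronous systemic response across
  neighbouring frontal channels — which is both physiologically sensible
  and within the method's representational capacity. Symmetric equal-gain
  lag groups are a related worst case: the second component becomes a
  cancelling difference mixture and is dropped.
* **Lag identifiability under periodic breathing.** With quasi-periodic
  free breathing the cross-correlation lag is only identifiable modulo the
  respiratory period; lag-recovery checks therefore use paced-protocol
  segments, whose changing rates break the ambiguity.

## Numerical choices

* 4 Hz rate grid; 0.25 s lag grid for coupling; 1024-point spectra over
  0–2 Hz; Burg order 16.
* The 2-s moving mean uses an odd, centred sample window truncated at the
  edges, with the series mean restored exactly afterwards.
* Rate values are clipped to stay positive after spline interpolation;
  z-scoring guards zero variance (<1e−12) by emitting zeros with a flag;
  the Wilcoxon permutation comparison uses a 1e−12 tolerance when counting
  ties at `p_obs`.
* Zero-phase `signal::filtfilt` leaves slowly decaying transients at the
  record edges (no special initial-condition handling); analyses that care
  operate away from the edges, and tests probe interior samples.
* Problem sizes in the validation suite — cohort of 19 for the paced
  spectral checks, 100 one-minute records for detector operating
  characteristics, 1000 null simulations for calibration — were chosen as
  the smallest sizes at which the group-level quantities are stable.

## Known limitations

* The Wilcoxon normal approximation deviates from the exact signed-rank
  distribution by up to ~0.07 in mid-tail p-values at n = 6–10; the
  approximation is the method as specified, and its agreement with exact
  enumeration is asserted in the extreme tail where the test is actually
  used for decisions.
* Single-lead ECG logic only; no arrhythmia classification beyond the
  ectopic-interval rule.
* No short-channel regression or motion correction for fNIRS; the
  band-pass plus PCA route is the only systemic-artifact handling.
* `run_study()` analyses a synthetic cohort; applying the pipeline to real
  recordings means constructing `multimodal_recording` objects from your
  own files (`read_recording()` documents the expected CSV/JSON layout).
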