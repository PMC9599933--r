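---
title: "Estimating heart and respiratory rates from chest-worn IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heart and respiratory rates from chest-worn IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imuvitals)
```

## The measurement problem

An IMU strapped to the sternum records two cardiorespiratory signatures at
once. Every ventricular ejection launches compression waves through the
thorax that appear as brief (~100 ms) vibration packets with energy
concentrated between roughly 10 and 40 Hz — the seismocardiogram (SCG) on
the accelerometer and the gyrocardiogram (GCG) on the gyroscope. Breathing
moves the whole chest wall slowly, adding a large 0.1–0.7 Hz oscillation.
`imuvitals` estimates heart rate (HR, bpm) and respiratory rate (RR, BrPM)
from these two signatures simultaneously, using one axis per sensor
(accelerometer z, gyroscope y — the axes the chest geometry favors), and
evaluates the estimates against reference ECG and respiration waveforms.

The estimator is deliberately spectral: no SCG fiducial points (MC/AO/AC/MO
peaks) are ever detected. Rates are read off as the dominant frequency of a
suitably conditioned signal, which is far more robust to morphology
variability than beat picking, at the cost of temporal smoothing controlled
by the analysis window length.

## Signal conditioning

**Cardiac chain** (`cardiac_preprocess()`), per posture segment:

1. *Axis selection* — `select_axis()` takes the configured channel
   unchanged.
2. *Wavelet band reconstruction 10–40 Hz* — `cwt_band_reconstruct()`
   evaluates an analytic Morlet filter bank (center parameter ω₀ = 6,
   16 voices per octave) at log-spaced scales whose center frequencies tile
   the band, sums the scales into a single frequency response, normalizes it
   to unit passband gain, and applies it as one zero-phase FFT-domain
   filter. The Gaussian passbands give much sharper band edges than the
   1st-order Butterworth alternative, which is the reason this stage exists:
   it must separate 10–40 Hz packets from respiratory energy three decades
   louder.
3. *Peak normalization* — division by the maximum absolute value. Peak
   location is scale invariant (a property the tests assert), so this stage
   only standardizes amplitudes across subjects and sensors.
4. *RMS envelope, 40 samples* (~330 ms at 120 Hz) — converts the packet
   train into a smooth, near-periodic pulse wave at the beat rate. The
   window is centered and shrinks at the edges, so length is preserved.
5. *Butterworth band-pass 0.7–3 Hz, order 1* — isolates the cardiac
   fundamental (42–180 bpm) of the envelope.

**Respiratory chain** (`respiratory_preprocess()`): axis selection followed
by the 0.1–0.7 Hz order-1 Butterworth band-pass (6–42 BrPM).

**References** (`reference_preprocess()`): the ECG gets the 0.7–3 Hz
band-pass, the respiration waveform the 0.1–0.7 Hz one, each at its native
sampling rate (250 / 25 Hz). Streams are never resampled; every stream is
analyzed on its own frequency grid, which the constant-resolution PSD below
makes directly comparable.

All filtering is zero-phase (forward–backward). Whether the original
analysis used zero-phase filters is unknowable from its description, but
peak-frequency estimation is phase-insensitive and zero-phase keeps the
mechanical and reference series aligned in time, which matters when pairing
them window by window.

## Constant-resolution sliding-window spectral estimation

`extract_rate_series()` segments each stream into windows of length
*L* ∈ {5, 15, 25, 35, 45, 55} s sliding by 1 s (a *T*-second segment yields
*T* − *L* + 1 windows), and computes per window a single-segment Welch PSD:
the taper spans the whole segment with 0% overlap, which degenerates to a
modified periodogram. Choices the method description leaves open:

* **Taper**: Hamming, the common default. For well-separated peaks the
  taper does not move the argmax.
* **Detrending**: the segment mean is removed before tapering, so DC
  leakage cannot masquerade as a 0.1 Hz-edge respiratory peak.
* **Zero padding**: to `NFFT = round(fs / Δf)` with Δf = 0.01/60 Hz
  ≈ 0.166 mHz — 0.01 bpm. The padded grid spacing `fs/NFFT` is then the
  *same* for all six window lengths and all three sampling rates, making
  estimates comparable across them; without it the 5 s window would have a
  24× coarser grid than the 55 s one.
* **Peak picking**: raw argmax within the physiological band, ties broken
  toward the lower frequency; no interpolation (the grid already resolves
  0.01 bpm). The rate is 60× the peak frequency.

Computing a 720,000-point FFT per window would dominate the runtime, so the
in-band bins are evaluated with a Bluestein chirp-z transform, which is
algebraically identical to the corresponding bins of the zero-padded FFT
(the tests assert equality to 1e-10) at a fraction of the cost. The
full-grid path remains available via `welch_psd(band = NULL)`.

One accuracy caveat is documented rather than hidden: for a 5 s window the
negative-frequency image of a tone interferes with its positive-frequency
peak on this very fine grid, biasing the argmax by up to ≈ 0.0013 Hz
(0.08 bpm). From 15 s upward the bias is below one grid bin.

**Invalid windows.** A window's estimate is flagged invalid (an `NA` gap,
never a number) when its in-band power falls below 1e-6 of the window's
total power, or when its total power falls below 1e-6 of the series' median
window power. The second floor exists because a zero-phase band-pass leaves
band-limited ringing inside a breath-hold: such windows have almost no
absolute power, yet nearly all of what remains is in-band, so a purely
relative floor would pass them. Invalid windows are excluded *pairwise*
from agreement statistics — whether the original study included
breath-hold windows in its RR statistics is not stated, and excluding them
is the defensible choice given that RR is spectrally undefined during
apnea.

## Agreement analysis

`bland_altman()` reports the mean of the differences (MOD) between
mechanical and reference rates and the limits of agreement
MOD ± 1.96·SD, with the sample (n−1) standard deviation — the conventional
95% interval. `mae()` is the mean absolute error. `build_report()` pools
all windows of all subjects within each sensor × posture × window-length
group into one set of differences (the source study pools the same way:
its scatter plots count subjects × windows as points) and adds a
per-subject MAE breakdown. No repeated-measures correction is applied for
the strong serial correlation of 1 s-step sliding windows; the LOA are
therefore descriptive of the pooled cloud, not inferential.

## The synthetic cohort

Because the recordings this pipeline targets are not public, validation
runs on a generative model (`subject_protocol()`,
`synthesize_subject()`) of exactly the structure the pipeline assumes:

* **Cardiac packets**: one Gaussian-windowed sinusoid per beat, carrier
  25 Hz, envelope SD 24 ms, truncated at ±60 ms. The carrier sits at the
  midpoint of the 10–40 Hz analysis band and the bandwidth is chosen so
  ≥ 95% of packet power lies inside it while the packet stays ≤ 120 ms.
  Beat instants integrate the instantaneous HR trajectory
  (`beat_times_from_hr()`), with the first-beat phase drawn per seed so
  packets never align systematically with window boundaries.
* **Respiration**: a sinusoid at the instantaneous RR, zeroed during
  breath-holds with a 0.5 s half-cosine taper so the amplitude drop adds no
  spectral splash. Real breathing is asymmetric (inspiration shorter than
  expiration); a pure tone is the simplest waveform with the correct
  fundamental, which is all a dominant-peak estimator uses.
* **Reference ECG**: a sharp Gaussian R-like spike (SD 20 ms) per beat plus
  a 0.25-amplitude beat-locked cosine at the cardiac fundamental. The
  second term stands in for the T-wave energy of a real ECG; without it a
  band-passed pure spike train has near-equal power at HR and 2×HR and the
  reference's dominant peak becomes ambiguous — real ECGs do not have that
  pathology, and neither should the emulation.
* **Postures and noise**: posture affects only the broadband Gaussian noise
  SD — lying 0.03 < sitting 0.05 < standing 0.15, in units of the cardiac
  packet amplitude. No quantitative per-posture SNR was available to match;
  the defaults reproduce the qualitative ordering (standing degrades
  accuracy) and are fixed, not fitted. Non-analysis axes carry
  0.3-attenuated copies of the analysis channels plus independent noise, so
  axis selection is testable without pretending to model chest
  biomechanics.
* **Default study protocol** (`default_protocol()`): one ~120 s segment per
  posture, each ending with a 20 s breath-hold; smooth sinusoidal HR
  (60–80 bpm) and RR (~9–21 BrPM) trajectories with seeded random base,
  amplitude, period and phase; 120 Hz IMU, 250 Hz ECG, 25 Hz respiration;
  1 Hz ground truth.

What passing tests on this cohort do **not** show: robustness to motion
artifacts (the emulated protocol is at rest), to SCG morphology variability
across subjects and sensor placements, to breathing harmonics from
asymmetric respiratory waveforms, or to reference-channel noise. The
generator is a structural emulation for validating the estimator's
signal-processing claims, not a biomechanical simulator.

## Numerical and degenerate-case choices

* PSD resolution is stored as the exact achieved spacing `fs/NFFT`; with
  the default Δf and the three standard rates these are identical floating
  point numbers (`1/6000`).
* `dominant_rate()` ties break toward the lower frequency
  (deterministically, via the first maximum).
* All-zero segments yield zero power and an invalid estimate, not an error;
  empty segments and bands outside the grid are errors.
* `rms_envelope()` uses a cumulative-sum formulation (O(n)) with centered
  windows shrinking at the edges; even window lengths place the extra
  sample to the right.
* Filters are designed with prewarped bilinear transforms
  (`signal::butter`), so the single-pass magnitude is exactly −3 dB at the
  cutoffs; the zero-phase application squares the response.
* Everything downstream of a `subject_protocol` is bit-deterministic given
  the seed; the generator restores the caller's RNG state.

## Problem sizes used in validation

The shipped tests validate parameter recovery on single 120 s subjects, the
accuracy bounds on a 5-subject single-posture cohort at sitting-level noise
(HR MAE < 1 bpm for L ≥ 25 s; RR MAE < 3 BrPM for L ≥ 15 s; 5 s windows
strictly worse than 25 s), and end-to-end byte-level determinism on a
3-subject, three-posture study replica. These sizes make the whole suite
run in minutes on one core while still exercising every pipeline stage at
the full default spectral resolution; the statistics scale with cohort size
only through pooling, not through any per-subject fitting, so small cohorts
are representative.

## Known limitations

* In-band argmax cannot disambiguate a harmonic that genuinely exceeds the
  fundamental; the conditioning stages exist to prevent that, but
  pathological morphologies could defeat them.
* During partial breath-hold overlap, windows mix quiet-breathing and
  apnea samples; their estimates lean on the surviving oscillation and are
  kept as valid.
* The LOA pool serially correlated windows, so they understate
  subject-level uncertainty.
* Sub-1 s rate dynamics are invisible by construction (1 s update, ≥ 5 s
  windows).
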