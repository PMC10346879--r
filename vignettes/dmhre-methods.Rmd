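---
title: "Methods: dual-modality rPPG heart-rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality rPPG heart-rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmhre)
```

## The problem and the signal model

Cardiac blood-volume changes modulate the light reflected by facial skin by
a few parts in ten thousand. Averaged over the skin pixels of a face region,
each colour channel of a video therefore carries a remote
photoplethysmogram (rPPG): a near-periodic component at the heart rate
riding on a large DC baseline, together with illumination drift, motion
artifacts and sensor noise. This package estimates the heart rate from such
multi-channel mean-intensity series — three RGB channels, optionally joined
by a near-infrared (NIR) channel from a dual-modality depth camera, whose
active IR illumination makes it far less sensitive to ambient light.

A window of `T` frames at `fs` Hz is processed as

1. **Amplitude-selective spectral gating** (`compute_psd()`,
   `masf_filter()`). Each channel is divided by its temporal mean (AC/DC
   normalisation) and Fourier transformed; `P_c(w)` denotes the amplitude
   `|X_c(w)|/T`, so a pulse of relative amplitude `a` appears as a bin of
   height `a/2`. A bin inside the evaluation band survives only if
   `P_NIR(w) <= alpha` *and* `P_B(w) <= beta (P_R(w) + P_G(w))`. The first
   condition exploits the cleanliness of the NIR spectrum: strong NIR
   energy at a bin marks motion rather than pulse. The second bounds the
   blue channel, which contributes the least pulse and the most noise in
   under-lit scenes. Rejected bins are multiplied by a small
   `suppression_weight` in **all** channels rather than zeroed — exact
   zeros can make the downstream ICA covariance singular.
2. **Chrominance fusion** (`assemble_M()`). The filtered RGB triple is
   converted per sample to CIELab, luminance is discarded, and the
   `(a*, b*)` chroma rows are stacked with the DC-normalised, mean-removed
   NIR row into a `3 x T` matrix. Chroma carries the haemoglobin signal
   while cancelling most common-mode illumination; dropping one row also
   trims the cost of every later stage.
3. **Stationary wavelet denoising** (`swt_ac2()`). Each row is decomposed
   by a 2-level undecimated (a-trous) sym4 transform and replaced by its
   level-2 approximation, removing the upper three quarters of the noise
   bandwidth while preserving length and time alignment.
4. **Robust PCA** (`pcp()`). The matrix is split as `M = L + S` by
   principal component pursuit — `min ||L||_* + lambda ||S||_1` subject to
   `M = L + S` — so that sparse outliers (motion spikes, tracking glitches)
   land in `S` while the smooth "background" `L` proceeds.
5. **Source separation and selection** (`jade()`, `select_rppg()`). JADE
   unmixes `L` into three components; the one with the most regular
   peak-to-peak spacing is taken as the rPPG candidate.
6. **Readout** (`bandpass()`, `spectral_peak_hr()`). The selected component
   is band-passed (order-10 Butterworth, zero phase) and the heart rate is
   read from the largest magnitude-spectrum bin inside the pass band:
   `bpm = 60 * f_peak`. No zero-padding is applied, so the bin width in bpm
   is exactly `b = 60 / Ls` for a window of `Ls` seconds — the resolution
   floor of this estimator (3 bpm at 20 s).

`run_window()` chains the stages; `sliding_estimate()` applies them on a
sliding grid (default step 6 frames, final full window always included);
`evaluate_hr()` scores estimates by MAE, RMSE, the SD of signed errors and
the fraction with absolute error strictly below 5 bpm.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `masf.alpha` | 0.004 (window <= 10 s), 0.003 (longer) | AC/DC amplitude | Sits just above the physiological pulse-amplitude band [1e-4, 2e-3]; shorter windows concentrate transient noise into taller bins and need the larger ceiling |
| `masf.beta` | 1.25 | — | Blue-restriction factor |
| `masf.suppression_weight` | 1e-4 | — | "Small but nonzero" attenuation of rejected bins |
| `masf.band` | 0.5–4 Hz | Hz | Where the gate's evidence is meaningful; bins outside are left to the final band-pass |
| `rpca.lambda` | `1/sqrt(max(dim))` | — | The standard pursuit weight |
| `rpca.tol`, `rpca.max_iter` | 1e-7, 2000 (500 for direct `pcp()` calls) | — | Feasibility stopping; the fixed-penalty iteration typically needs 100–1500 steps on pipeline windows |
| `hr.band_hz` | 0.83–2.4 Hz (50–144 bpm) | Hz | Adult resting-to-elevated range; a wider 0.67–2.4 Hz band suits RGB-only footage |
| `select.prominence_frac` | 0.25 | fraction of component SD | Peaks smaller than a quarter of the signal's spread are treated as noise |

The ablation variants mirror the stage ladder: `baseline` uses the classic
single-channel amplitude gate (R-channel ceiling 0.002, the upper edge of
the pulse band) with ICA and the spectral readout; `p1` adds wavelet
denoising; `p2` replaces the gate with the dual-modality version; `p3`
(default) adds the robust-PCA split.

## What the synthetic generator emulates

`generate_clip()` builds each channel as
`dc_c (1 + a_c [sin(2 pi f0 t) + h sin(4 pi f0 t)] + interference + drift +
spikes + noise)`:

* pulse amplitudes `a_c` of 5e-4 / 1e-3 / 7e-4 / 6e-4 for R/G/B/NIR —
  inside the physiological band, green strongest, then blue, then red —
  with a 20 % second harmonic;
* five 3-frame triangular motion spikes of 1 % DC with random sign;
* sinusoidal illumination drift of 0.3 % DC at 0.1 Hz;
* white noise of 2e-4 DC per frame. This is the noise floor of a
  whole-face spatial average: ~2 digital numbers of per-pixel sensor noise
  divided by the square root of the >= 10^4 skin pixels contributing to
  each frame mean, relative to a baseline near 130;
* optional narrowband interference tones with per-channel amplitudes,
  emulating the in-band noisy peaks of rhythmic motion (strong in the
  active-IR NIR band) and of blue-heavy dark-scene noise — the regime in
  which amplitude thresholds on RGB spectra alone cannot distinguish true
  from noisy heart-rate peaks;
* a dark mode that halves every DC and raises the RGB noise to 0.5 % DC
  (per-bin noise amplitudes then rival the pulse peak) while leaving the
  NIR noise untouched.

Everything is determined by one integer seed. The generator does **not**
emulate skin-tone diversity, face-tracker jitter, nonstationary heart
rates, ballistocardiographic waveform shape, or video-compression loss —
so green tests demonstrate correct mechanism under the stated signal
model, not field performance on arbitrary footage.

The test batteries use 20 s clips at 30 Hz with heart rates uniform on
55–140 bpm: 50 clips under the moderate defaults for end-to-end recovery
and 25 clips with the two interference tones for the ablation comparison —
sizes chosen to keep the full suite under a minute while leaving the
binomial noise on the reported rates small.

## Numerical choices and degenerate inputs

* **Spectral gate.** Transform coefficients are suppressed pairwise with
  their conjugate bins, keeping the inverse transform exactly real; each
  channel's DC is restored afterwards. Bins whose total amplitude is
  numerical dust (< 1e-10 of the spectrum maximum) carry no evidence and
  are never counted as suppressed. A channel with zero temporal mean makes
  AC/DC normalisation undefined and is a hard error naming the channel.
* **Colour conversion.** sRGB companding with the D65 white point (the
  consumer-camera default); values are clipped to [0, 255] before
  conversion, with a warning beyond a half-intensity ringing tolerance.
* **Wavelet stage.** The a-trous filters are normalised to unit DC gain,
  so constants pass through unchanged; boundaries are periodic, which
  makes the transform exactly shift-covariant, and lengths that are not a
  multiple of `2^levels` are symmetric-padded and cropped back. At 30 Hz
  the level-2 approximation band is 0–3.75 Hz rather than the nominal
  0–2 Hz of an 8 Hz dyadic ladder; no resampling is performed — the final
  band-pass enforces the heart-rate band regardless, and `wd.keep = "DC2"`
  remains available for subjects expected above ~130 bpm.
* **Robust PCA.** The augmented-Lagrangian iteration runs from a zero
  initialisation with a fixed penalty `mu = n1 n2 / (4 ||M||_1)` and stops
  on the relative feasibility residual. Rows are standardised before the
  split so the chroma and NIR scales do not distort the nuclear/l1
  trade-off. Two properties of the pursuit at this matrix shape deserve
  honesty: with only three rows the low-rank factor is maximally coherent,
  so the exact-recovery guarantees of pursuit theory do not apply, and on
  pulse-dominated windows the convex optimum can collapse `L` below full
  rank. `run_window()` therefore uses `L` only when it retains all three
  directions (relative condition > 1e-6) and otherwise proceeds with the
  wavelet output; the choice is recorded per window in the diagnostics
  (`rpca_used`). In practice the split engages exactly where it is needed
  — noisy, motion-corrupted windows whose rows decorrelate.
* **JADE.** Whitening uses the eigen-decomposition of the row covariance;
  a covariance that is rank-deficient (relative eigenvalue below 1e-12) is
  a hard error that points at the low-rank stage. The full set of
  fourth-order cumulant matrices is jointly diagonalised by Jacobi
  rotations with threshold `1e-8 / sqrt(T)` on `|sin(theta)|`.
* **Component selection.** The paper-level rule — least SD of successive
  peak distances — is underdetermined, so the implementation fixes:
  minimum peak separation of one shortest physiological beat interval
  (`fs * 60 / hr_high` samples), prominence of at least a quarter of the
  component SD, and both polarities scored (ICA leaves the sign free),
  ties broken by the lower index. Peaks are located on a band-limited copy
  of each component so slow drift cannot scramble the interval statistics,
  while the prominence threshold stays tied to the raw SD — an aperiodic
  component whose band-limited residue is tiny can then never win. A
  component with fewer than three peaks scores infinity; all-infinite is
  an error.
* **Band-pass.** Order-10 Butterworth applied forward-backward. The
  direct-form realisation was verified stable for the narrow heart-rate
  bands used here (pass gain 0.999 at the band centre, 47 dB attenuation
  at 0.1 Hz for fs = 30).
* **Readout.** The estimate is always a bin centre inside the configured
  band, so it inherits the `60/Ls` quantisation; windows shorter than one
  second are rejected.

## Known limitations

* The recovery batteries characterise the method under its own signal
  model; real-data error levels (several bpm MAE on public benchmarks for
  methods of this family) are governed by tracking quality and compression
  that the generator does not simulate.
* Heart rates within half a bin of the band edges, or at exactly half-bin
  offsets of very low rates, occasionally mislead the peak-regularity
  selection when a noise component's band-limited peak train happens to be
  regular; at the 20 s default this affects a few percent of clips.
* The rule-based skin masks (YCbCr chroma box, Otsu) are adequate for the
  synthetic frontend and controlled footage but are not a substitute for a
  trained segmenter on real video; both are pluggable behind
  `skin_mask(mode = "external")`.
* With three input rows the robust-PCA stage cannot enjoy pursuit's
  exact-recovery guarantees (see above); it acts as a safeguarded outlier
  filter, not a certified decomposition.
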