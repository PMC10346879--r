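# dmhre — dual-modality RGB-NIR remote heart-rate estimation

Heartbeats modulate the light reflected by facial skin by a few parts in
ten thousand. Spatially averaging the skin pixels of a face region turns a
video into a small set of channel time series — R, G, B and, with a
dual-modality depth camera, a near-infrared (NIR) channel whose active
illumination is far less sensitive to ambient light. `dmhre` recovers the
remote photoplethysmogram (rPPG) from such series and reads the heart rate
from its spectral peak. It is written for researchers working on
camera-based vital-sign monitoring who need a transparent, scriptable
reference chain and a fully synthetic test bed.

## The method

For a window of `T` frames at `f_s` Hz the chain is:

1. **Amplitude-selective gating.** With `P_c(w)` the amplitude spectrum of
   the DC-normalised channel `c`, a bin survives only if

       P_NIR(w) <= alpha        and        P_B(w) <= beta (P_R(w) + P_G(w)),

   with `alpha = 0.003–0.004` (just above the physiological pulse band
   `[1e-4, 2e-3]` of AC/DC amplitudes) and `beta = 1.25`. Rejected bins are
   attenuated by `1e-4` in every channel. Strong NIR energy marks motion;
   a dominant blue amplitude marks noise. Without an NIR channel the first
   condition is skipped.
2. **Chrominance fusion.** The filtered RGB is mapped to CIELab, luminance
   is discarded, and `(a*, b*)` are stacked with the normalised NIR row
   into `M` (3 × T).
3. **Wavelet denoising.** Each row is replaced by the level-2 approximation
   of a stationary (undecimated) sym4 transform.
4. **Robust PCA.** `M̂ = L + S` by principal component pursuit,
   `min ‖L‖* + λ‖S‖₁` s.t. `M̂ = L + S`, `λ = P^(-1/2)` with `P` the larger
   dimension; sparse outliers land in `S`, the background `L` proceeds.
5. **JADE ICA + selection.** `L` is unmixed into three components; the one
   with the most regular peak-to-peak spacing is the rPPG candidate.
6. **Readout.** Order-10 zero-phase Butterworth band-pass (0.83–2.4 Hz =
   50–144 bpm), then `bpm = 60 · f_peak` from the largest spectrum bin —
   without zero-padding, so a window of `L_s` seconds resolves
   `b = 60 / L_s` bpm (3 bpm at 20 s).

Accuracy is reported as MAE, RMSE, SD of signed errors, and
`Acc = DS / DT`, the fraction of estimates with error strictly below 5 bpm.

## Worked example

```r
library(dmhre)

clip <- generate_clip(synthetic_spec(hr_bpm = 72, seed = 7))  # 20 s @ 30 Hz
est  <- run_window(clip$series)                               # full chain (P3)
est
#> <hr_estimate> 72.0 bpm (peak 1.200 Hz, resolution 3.00 bpm)

sl <- sliding_estimate(clip$series, window_len = 300, step = 150,
                       gt = clip$truth)
sl
#>  window_start bpm peak_hz resolution_bpm gt_bpm
#>             0  72     1.2              6     72
#>           150  72     1.2              6     72
#>           300  72     1.2              6     72

evaluate_hr(sl$bpm, sl$gt_bpm)
#> <eval_report> n=3  MAE=0.00  RMSE=0.00  SD=0.00  Acc(5bpm)=1.000 (3/3)
```

The moderate-corruption clip (five motion spikes, illumination drift,
sensor noise) is recovered exactly at the 3 bpm bin resolution of a 20 s
window; the 10 s sliding windows resolve 6 bpm. Diagnostics attached to
each estimate record the suppressed-bin count, robust-PCA iterations and
whether its split was used, and the peak-regularity scores behind the
component choice.

A command-line front end is installed with the package
(`system.file("exec/dmhre", package = "dmhre")`):

```sh
dmhre synth    --hr 72 --seconds 20 --seed 1 --out clip.csv
dmhre estimate --input clip.csv --variant p3 --out est.csv
dmhre evaluate --pred est.csv --gt clip_gt.csv
dmhre ablate   --n 25 --seed 1
dmhre run      --config job.yml
```

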