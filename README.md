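# rppg — contactless heart-rate estimation from video

`rppg` measures heart rate (HR) without skin contact, from ordinary RGB
video of a face. The cardiac pulse modulates the volume of blood under
the skin, and with it the light the skin reflects; averaged over a
suitable region of interest (ROI, here the forehead, where the
photoplethysmographic signal is strongest), the per-frame mean color
carries a periodic component at the pulse frequency. This *remote
photoplethysmography* (rPPG) signal is tiny — a fraction of one 8-bit
intensity step — so recovering it takes a careful measurement chain.
The package is aimed at researchers and engineers building or
validating camera-based vital-sign monitors, and ships a synthetic
pulsatile-video generator so every stage is verifiable without human
subjects.

## The method

For each analysis window (30 s long, sliding by 1 s, so one estimate
per second after the first 30 s):

1. **ROI** — the face box and an 81-point landmark set (68 standard
   points + 13 forehead points) define a forehead polygon, rasterized
   to a per-frame mask. Backends are pluggable; a deterministic
   geometric backend and a patch detector cover testing, with the usual
   model-based detectors as an interface.
2. **Optional low-light enhancement** — double-plateau histogram
   equalization of ROI luminance, the two plateau limits chosen by a
   seeded cuckoo-search optimizer maximizing the entropy sum of the
   clipped sub-histograms (off by default).
3. **Trace** — per-frame arithmetic mean of R, G, B over the mask.
4. **Conditioning** — per channel: linear detrend, normalization
   (per-channel mean division by default; max-abs available),
   5-point moving average, and a zero-phase third-order Butterworth
   band-pass over 0.7–4 Hz (= 42–240 bpm).
5. **Chrominance projection (CHROM)** —

   ```
   X(t) = 3 R(t) − 2 G(t)
   Y(t) = 1.5 R(t) + G(t) − 1.5 B(t)
   rPPG(t) = X(t) − μ Y(t),   μ = σ(X) / σ(Y)
   ```

   Achromatic variation (equal on all channels, e.g. illumination
   flicker) gives X = Y and μ = 1, so it cancels exactly.
6. **Spectral readout** — Hann taper, zero-padding to ≥ 2^15 points
   (grid < 0.5 bpm), and `HR = 60 · f_peak` with the peak restricted
   to the pass band.

Estimates are scored against a ground-truth series (e.g. a pulse
oximeter) by the fraction of windows with absolute error strictly
below 3 bpm, plus MAE and RMSE.

## Worked example

```r
library(rppg)
d <- tempfile()
cfg <- synth_config(hr_bpm = 72, fps = 30, duration_s = 60,
                    noise_sd = 0.4, seed = 7)
paths <- write_synthetic_video(cfg, d)           # video.ppm, gt.csv, roi.json
res <- rppg_run(rppg_config(source = paths$video,
                            roi = paths$roi, truth = paths$gt))
head(res$estimates, 3)
#>   window_start_s  f_hr_hz   hr_bpm    quality
#> 1              0 1.201172 72.07031 0.01554223
#> 2              1 1.200256 72.01538 0.01567979
#> 3              2 1.200256 72.01538 0.01586617
res$report
#> HR evaluation over 31 windows: accuracy (|err| < tol) 100.00%, MAE 0.027 bpm, RMSE 0.032 bpm
```

A 60 s recording yields 31 sliding windows; every window recovers the
true 72 bpm to within a few hundredths of a bpm (`f_hr_hz` is the
spectral peak, `hr_bpm = 60 · f_hr_hz`, `quality` the peak's share of
in-band power). The same run from the shell:

```sh
rppg synth --out demo --hr 72 --duration 60 --noise-sd 0.4 --seed 7
rppg run --source demo/video.ppm --roi demo/roi.json --truth demo/gt.csv
```

## Scope

Offline, single-subject analysis of video files. Live-camera capture,
model-based landmark runtimes (dlib/mediapipe), alternative pulse
extractors (GREEN/PCA/ICA/POS), peak-detection HR and HRV are out of
scope; see `vignettes/rppg-methods.Rmd` for design rationale and
limitations.
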