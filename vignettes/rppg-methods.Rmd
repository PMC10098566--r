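---
title: "Methods: chrominance-based remote photoplethysmography in rppg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chrominance-based remote photoplethysmography in rppg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Cardiac activity modulates the blood volume under the skin, and blood
absorbs light more strongly than the surrounding tissue, so the color
of light reflected from skin carries a small periodic component at the
pulse frequency. A consumer camera sees this as sub-intensity
fluctuations of the mean ROI color — typically well below one 8-bit
step, recoverable only because averaging thousands of ROI pixels gives
the mean far more resolution than a single pixel has. `rppg`
implements the full chain from frames to beats-per-minute, together
with a synthetic generator that makes each stage falsifiable.

Assumptions inherited from the method family: near-white, slowly
varying illumination; a mostly frontal, mostly still face; uniform
nominal frame sampling; and a pulse rate inside 0.7–4 Hz (42–240 bpm).

## Pipeline stages and their parameters

| Stage | Parameter | Default | Units | Why |
|---|---|---|---|---|
| Windowing | `window_s` | 30 | s | long enough for a stable spectral peak; one estimate per `slide_s` |
| Windowing | `slide_s` | 1 | s | 1 Hz estimate stream after the first 30 s |
| Band | `f_low`, `f_high` | 0.7, 4.0 | Hz | physiological HR range, 42–240 bpm |
| Smoothing | `smooth_w` | 5 | samples | mild high-frequency noise reduction; must be odd |
| Filter | `order` | 3 | — | third-order Butterworth prototype (6th-order band-pass) |
| Filter | `method` | `butterworth` | — | `ideal` (FFT brick-wall) kept for comparison |
| Conditioning | `normalization` | `mean` | — | see below; `maxabs` is the literal alternative reading |
| Readout | zero-padding | ≥ 2^15 | points | spectral grid < 0.5 bpm; a bare 30 s window resolves only 2 bpm |
| Evaluation | `tol_bpm` | 3 | bpm | hit ⇔ \|est − truth\| **<** 3 (strict: "falls below") |
| Enhancement | `n_nests`, `pa`, `iterations` | 15, 0.25, 50 | — | customary cuckoo-search settings; seeded |

The stage order per channel is detrend → normalize → smooth →
band-pass, each length-preserving; the detrend/smooth/band-pass
operators are linear (tested to 1e-9).

## The normalization decision

The chrominance projection is

X = 3R − 2G, Y = 1.5R + G − 1.5B, rPPG = X − μY, μ = σ(X)/σ(Y),

with population (1/N) standard deviations — the 1/N vs 1/(N−1) choice
cancels in the ratio but is fixed for bit-exact tests. The projection's
defining robustness property is achromatic cancellation: if R = G = B
(equal-channel illumination variation), then X = Y, μ = 1 and rPPG ≡ 0.

That property interacts sharply with how channels are normalized
beforehand. If each channel is rescaled to unit maximum absolute value,
then a noise-free pulse that modulates all channels *proportionally* —
which is exactly what a clean single-source signal model produces —
becomes the *same* waveform in R, G and B, i.e. an achromatic input,
and is cancelled identically. The readout is then decided by rounding
noise. The package therefore defaults to the original chrominance
normalization: each detrended channel is divided by its temporal mean
intensity, which preserves the *relative* pulsatile amplitudes between
channels (green strongest) that the projection needs. The max-abs
variant remains available (`normalization = "maxabs"`) because it is a
defensible literal reading of the pipeline description this package
follows; both are exposed, one is documented as default, and the
end-to-end recovery suite runs on the default.

Degenerate windows: σ(Y) = 0 (constant channels) flags the pair, μ is
reported as 0 and rPPG = X by the formula; an identically-zero pulse
yields a no-signal estimate (`f_hr = NA`, quality 0) rather than an
arbitrary number. All-zero windows pass through max-abs normalization
unchanged for the same reason.

## Spectral readout

Hann taper, zero-padding to `max(2^15, next power of two ≥ n)`, power
spectrum by FFT, argmax restricted to the pass band; ties break toward
the lower frequency for determinism. `hr_bpm = 60 · f_hr` exactly.
The quality figure is the peak bin's share of total in-band power —
a relative signal-concentration index in [0, 1], not a calibrated SNR.

## Filtering numerics

No DSP library ships in the supported environment, so the band-pass is
designed in-package: analog Butterworth prototype poles, low-pass to
band-pass transform (order doubles), bilinear transform with frequency
pre-warping. Zero-phase application runs the filter forward and
backward over an odd-extension padded signal with steady-state initial
conditions. Padding length is `max(3·(filter length−1), 3·fps/f_low)`
samples, because the low band edge (0.7 Hz) dominates the transient
extent. Coefficients and the forward-backward output are pinned in the
test suite against values frozen from an independent reference design
at matched padding.

## ROI geometry

The 81-point schema is the standard 68-point layout plus 13 forehead
points (indices 69–81, 1-based). The forehead polygon runs along the
13 forehead points (left→right) and closes along the 10 eyebrow points
(right→left). Rasterization uses the even-odd rule evaluated at pixel
centers: vertices live in continuous 0-based coordinates, pixel
(row i, col j) covers [j−1, j) × [i−1, i) with center (j−0.5, i−0.5).
This convention is stated so mask tests can be bit-exact against a
brute-force point-in-polygon oracle. Degenerate landmark sets — zero
polygon area, or forehead points not above the eyebrow line (a flipped
detection) — yield an empty mask, which invalidates the sample; the
pipeline reuses the last valid mask for at most `fps` consecutive
frames before declaring samples invalid, and windows containing
invalid samples are dropped (no interpolation) and counted.

The heavy landmark detectors are deliberately behind a backend
interface: the deterministic geometric backend and the luminance-patch
detector make the measurement chain testable without model files; the
dlib-style backend validates its model path but has no runtime here.

## Low-light enhancement

The luminance (BT.601) histogram is split at an Otsu threshold; both
sub-histograms are clipped between a lower and an upper plateau (counts
above the upper are capped, nonzero counts below the lower are raised),
and a per-segment equalization mapping is built from the clipped
cumulative distributions — monotone nondecreasing by construction, and
reducing to plain per-segment equalization when the plateaus are
disabled. The plateau pair maximizes the sum of Shannon entropies of
the two clipped sub-histograms, searched by a seeded cuckoo search
(Lévy flights, elitism: never worse than the best initial nest; zero
iterations return the best initial candidate). The upstream description
this package follows does not specify the objective, the
hyper-parameters, or the plateau formulas, so all are documented
defaults exposed in configuration, not claims about any particular
published variant.

Otsu tie rule: thresholds between two separated modes tie exactly on
between-class variance; the plateau midpoint (floor of the mean of the
tied maximizers) is returned, centering the threshold between the
modes. A uniform histogram has the unique maximizer 127.

Enhancement shifts all three channels of a pixel by the same luminance
delta, so the chromatic differences (R−G, G−B) that carry the pulse
are preserved exactly wherever no 8-bit clipping occurs. The stage is
off by default: it exists for dim scenes and can misbehave under
natural light, so the default measurement chain stays minimal.

## The synthetic world

`synth_config()` states the simulated recording: a skin-colored patch
(`baseline_rgb = (150, 110, 95)`) whose mean color carries a sinusoid
at `hr_bpm/60` Hz with channel weights (0.3, 1.0, 0.6) — green
dominant, as the blood-volume signal is in real skin; the exact
physiological ratios are not fixed by the source material, so these are
test-oriented defaults, chosen once. Corruptions: i.i.d. Gaussian
sensor noise per channel (`noise_sd`), an achromatic 0.05 Hz
illumination drift (below the pass band), an achromatic flicker tone
(`flicker_hz`/`flicker_amp` — the amplitude field is this package's
addition, since a flicker frequency alone does not define a component),
and an optional second harmonic (`harmonic_rel`) to exercise
peak-picking. Drift and flicker are equal across channels *by
construction* so that the chrominance cancellation property is testable.
Everything is reproducible from `seed`; 8-bit clipping is applied after
summing components and logged as a warning.

`generate_video()` renders the patch centered over a static background
and quantizes to 8 bits, so the ROI mean reproduces the trace within
±0.5 intensity units; the ground-truth sidecar is emitted at 1 Hz,
emulating a pulse-oximeter reference.

What the generator does **not** emulate: head motion, specular
highlights, skin-tone optics, rolling-shutter effects, compression
artifacts, spatially textured skin, detector jitter. A green recovery
suite therefore establishes that the signal chain is correct, not that
field accuracy on human subjects is reached; the published accuracies
the method family reports on human cohorts are not reproducible without
the cohort and are out of scope here.

## Other stated choices

* Windows are emitted only when complete (a fixed 30 s acquisition
  yields exactly one window); window k starts at k·`slide_s` exactly,
  up to fps rounding.
* Ground-truth alignment for a window is the mean of reference samples
  inside [start, start+window); windows without reference samples are
  excluded and logged.
* Estimate streams start at t = 30 s (first full window), then one per
  second — the sliding is prospective, not retrospective.
* Video files are lossless concatenated P6 PPM streams (+ JSON fps
  sidecar): no codec dependency exists in the supported environment,
  and lossy compression would destroy the sub-intensity signal.
  Internal channel order is fixed to (R, G, B) at the I/O boundary; the
  projection is channel-asymmetric, so a silent B↔R swap corrupts μ —
  round-trip tests guard this.
* Variable-frame-rate input is outside the file format; the pipeline
  assumes the declared nominal fps.

## Known limitations

No motion compensation; single subject (largest face wins); the patch
detector is for synthetic/controlled frames, not natural scenes; live
capture and model-based landmark runtimes are interface stubs in this
build; HR only (no HRV, no peak-domain analysis).
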