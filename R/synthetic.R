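# Synthetic pulsatile data: RGB traces and rendered videos with known
# ground-truth heart rate, standing in for webcam recordings of a subject.
# The optical premise is that reflected skin light is modulated by the
# blood volume under the skin, strongest in the green channel; the
# generator adds that modulation to a skin-colored baseline together with
# controllable corruptions (sensor noise, achromatic flicker, slow
# illumination drift).

#' Configuration for the synthetic pulsatile-signal generator
#'
#' Describes a simulated recording: a skin-colored patch whose mean color
#' carries a sinusoidal pulsatile component at a known heart rate, plus
#' optional corruptions. All amplitudes are in 8-bit intensity units.
#'
#' @param hr_bpm Heart rate of the simulated pulse, beats per minute.
#' @param fps Frame rate, frames per second.
#' @param duration_s Recording length in seconds.
#' @param pulse_amplitude Peak amplitude of the pulsatile component before
#'   channel weighting (intensity units).
#' @param baseline_rgb Length-3 numeric, mean skin color (R, G, B) in
#'   `[0, 255]`. Default is a generic skin tone.
#' @param channel_weights Length-3 numeric, relative pulse strength per
#'   channel. Default `c(0.3, 1.0, 0.6)`: green-dominant, consistent with
#'   the green channel tracking the blood-volume pulse most strongly.
#' @param harmonic_rel Relative amplitude of an optional second harmonic
#'   of the pulse (tests peak-picking robustness); 0 disables it.
#' @param noise_sd Standard deviation of i.i.d. Gaussian sensor noise per
#'   channel (intensity units).
#' @param illum_drift_amp Amplitude of a slow (0.05 Hz, below the 0.7 Hz
#'   analysis band) achromatic illumination drift.
#' @param flicker_hz Frequency of an achromatic flicker tone; with
#'   `flicker_amp`, equal on all three channels so that chrominance
#'   projection cancels it by construction.
#' @param flicker_amp Amplitude of the achromatic flicker (intensity units).
#' @param seed Integer seed; every stochastic component is reproducible
#'   from it.
#'
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(hr_bpm = 72, fps = 30, duration_s = 30)
synth_config <- function(hr_bpm = 72, fps = 30, duration_s = 30,
                         pulse_amplitude = 2,
                         baseline_rgb = c(150, 110, 95),
                         channel_weights = c(0.3, 1.0, 0.6),
                         harmonic_rel = 0,
                         noise_sd = 0,
                         illum_drift_amp = 0,
                         flicker_hz = 0,
                         flicker_amp = 0,
                         seed = 1L) {
  stopifnot_scalar_pos(hr_bpm, "hr_bpm")
  stopifnot_scalar_pos(fps, "fps")
  stopifnot_scalar_pos(duration_s, "duration_s")
  if (!is.numeric(baseline_rgb) || length(baseline_rgb) != 3L ||
      any(baseline_rgb < 0) || any(baseline_rgb > 255)) {
    stop("`baseline_rgb` must be three values in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(channel_weights) || length(channel_weights) != 3L) {
    stop("`channel_weights` must be three numbers", call. = FALSE)
  }
  if (pulse_amplitude < 0 || noise_sd < 0 || illum_drift_amp < 0 ||
      flicker_amp < 0 || harmonic_rel < 0) {
    stop("amplitudes must be nonnegative", call. = FALSE)
  }
  structure(
    list(hr_bpm = hr_bpm, fps = fps, duration_s = duration_s,
         pulse_amplitude = pulse_amplitude, baseline_rgb = baseline_rgb,
         channel_weights = channel_weights, harmonic_rel = harmonic_rel,
         noise_sd = noise_sd, illum_drift_amp = illum_drift_amp,
         flicker_hz = flicker_hz, flicker_amp = flicker_amp,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic RGB mean-color trace
#'
#' Produces the per-frame mean-color sequence a camera would observe over
#' a pulsatile skin patch: per channel,
#' `baseline + w_c * A * (sin(2*pi*f*t) + h * sin(4*pi*f*t)) + drift(t) +
#' flicker(t) + noise`, clipped to `[0, 255]`. Drift and flicker are
#' achromatic (identical on R, G, B).
#'
#' @param config A [synth_config()].
#' @return An [rgb_trace()] with `round(fps * duration_s)` samples per
#'   channel. A warning is issued if clipping to the 8-bit range occurred.
#' @export
#' @examples
#' tr <- generate_trace(synth_config(hr_bpm = 72, fps = 30, duration_s = 10))
#' length(tr$g)  # 300
generate_trace <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("`config` must be a synth_config", call. = FALSE)
  }
  n <- round(config$fps * config$duration_s)
  t <- (seq_len(n) - 1) / config$fps
  f <- config$hr_bpm / 60
  pulse <- sin(2 * pi * f * t)
  if (config$harmonic_rel > 0) {
    pulse <- pulse + config$harmonic_rel * sin(2 * pi * 2 * f * t)
  }
  drift <- if (config$illum_drift_amp > 0) {
    config$illum_drift_amp * sin(2 * pi * 0.05 * t)
  } else {
    0
  }
  flicker <- if (config$flicker_amp > 0 && config$flicker_hz > 0) {
    config$flicker_amp * sin(2 * pi * config$flicker_hz * t)
  } else {
    0
  }
  chans <- with_seed(config$seed, {
    lapply(1:3, function(ci) {
      noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
      config$baseline_rgb[ci] +
        config$channel_weights[ci] * config$pulse_amplitude * pulse +
        drift + flicker + noise
    })
  })
  clipped <- sum(vapply(chans, function(x) sum(x < 0 | x > 255), 0))
  if (clipped > 0) {
    warning(sprintf("%d samples clipped to the 8-bit range", clipped),
            call. = FALSE)
  }
  rgb_trace(clip8(chans[[1]]), clip8(chans[[2]]), clip8(chans[[3]]),
            fps = config$fps)
}

#' Render a synthetic video with a declared pulsatile ROI
#'
#' Renders frames in which a centered rectangular patch (the declared ROI,
#' `roi_fraction` of each dimension) carries the [generate_trace()] color,
#' quantized to 8 bits, over a static background. Ground truth is emitted
#' at 1 Hz, emulating a pulse-oximeter sidecar.
#'
#' @param config A [synth_config()].
#' @param width,height Frame dimensions in pixels.
#' @param roi_fraction Fraction (0, 1] of each dimension covered by the
#'   patch.
#' @return A list with `frames` (list of `height x width x 3` integer
#'   arrays), `fps`, `mask` (logical matrix, the declared ROI),
#'   `box` (list x, y, w, h; 0-based top-left), `trace` (the underlying
#'   unquantized [rgb_trace()]) and `gt` (data.frame `time_s`, `hr_bpm`).
#' @export
generate_video <- function(config, width = 64, height = 48,
                           roi_fraction = 0.5) {
  if (!is_count(width) || !is_count(height) || width <= 0 || height <= 0) {
    stop("`width` and `height` must be positive integers", call. = FALSE)
  }
  if (roi_fraction <= 0 || roi_fraction > 1) {
    stop("`roi_fraction` must be in (0, 1]", call. = FALSE)
  }
  trace <- generate_trace(config)
  n <- length(trace$r)
  pw <- max(1L, round(width * roi_fraction))
  ph <- max(1L, round(height * roi_fraction))
  x0 <- (width - pw) %/% 2L
  y0 <- (height - ph) %/% 2L
  mask <- matrix(FALSE, height, width)
  mask[(y0 + 1):(y0 + ph), (x0 + 1):(x0 + pw)] <- TRUE
  bg <- c(40L, 40L, 40L)
  frames <- vector("list", n)
  base <- array(0L, dim = c(height, width, 3))
  for (ci in 1:3) base[, , ci] <- bg[ci]
  for (i in seq_len(n)) {
    fr <- base
    fr[, , 1][mask] <- as.integer(round(trace$r[i]))
    fr[, , 2][mask] <- as.integer(round(trace$g[i]))
    fr[, , 3][mask] <- as.integer(round(trace$b[i]))
    frames[[i]] <- fr
  }
  gt_t <- seq(0, floor(config$duration_s - 1e-9))
  list(frames = frames, fps = config$fps, mask = mask,
       box = list(x = x0, y = y0, w = pw, h = ph),
       trace = trace,
       gt = data.frame(time_s = gt_t,
                       hr_bpm = rep(config$hr_bpm, length(gt_t))))
}

#' Write a synthetic video plus its sidecars to disk
#'
#' Writes the rendered video (lossless PPM stream, see [write_video()]),
#' the 1 Hz ground-truth CSV (`time_s,hr_bpm` header) and a JSON file
#' declaring the ROI box, so a full pipeline run can be driven from files
#' alone. A heart rate outside the readable 42-240 bpm band is generated
#' anyway but logged with a warning.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @param width,height,roi_fraction Passed to [generate_video()].
#' @return Invisibly, a named list of the written paths
#'   (`video`, `gt`, `roi`).
#' @export
write_synthetic_video <- function(config, out_dir, width = 64, height = 48,
                                  roi_fraction = 0.5) {
  if (config$hr_bpm < 42 || config$hr_bpm > 240) {
    warning(sprintf(
      "hr_bpm = %g is outside the readable 42-240 bpm band", config$hr_bpm),
      call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vid <- generate_video(config, width, height, roi_fraction)
  video_path <- file.path(out_dir, "video.ppm")
  write_video(vid$frames, video_path, fps = vid$fps)
  gt_path <- file.path(out_dir, "gt.csv")
  write.csv(vid$gt, gt_path, row.names = FALSE, quote = FALSE)
  roi_path <- file.path(out_dir, "roi.json")
  jsonlite::write_json(vid$box, roi_path, auto_unbox = TRUE)
  invisible(list(video = video_path, gt = gt_path, roi = roi_path))
}
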