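# Chrominance-based pulse extraction and spectral heart-rate readout.
#
# The conditioned channel traces are projected onto two chrominance
# axes,
#     X(t) = 3 R(t) - 2 G(t)
#     Y(t) = 1.5 R(t) + G(t) - 1.5 B(t),
# and combined as rPPG(t) = X(t) - mu Y(t) with mu = sd(X) / sd(Y)
# (population standard deviations). Under white illumination, light
# reflected from skin moves all three channels together, so achromatic
# variation (R = G = B) cancels identically: X = Y = s, mu = 1,
# rPPG = 0. The heart rate is the frequency of the maximum power-
# spectrum peak within the pass band, times 60.

#' Project a conditioned window onto the chrominance axes
#'
#' Computes `x = 3R - 2G`, `y = 1.5R + G - 1.5B` and
#' `mu = sd(x) / sd(y)` (population standard deviations). When
#' `sd(y) = 0` the pair is flagged degenerate and `mu = 0` is reported.
#'
#' @param window A `conditioned_window` (or any list with equal-length
#'   numeric `r`, `g`, `b`).
#' @return A `chrom_pair`: list `x`, `y`, `mu`, `degenerate`.
#' @export
chrom_project <- function(window) {
  r <- window$r; g <- window$g; b <- window$b
  n <- length(r)
  if (length(g) != n || length(b) != n) {
    stop("channels must have equal length", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- 3 * r - 2 * g
  y <- 1.5 * r + g - 1.5 * b
  sy <- sd_pop(y)
  if (sy == 0) {
    mu <- 0
    degenerate <- TRUE
  } else {
    mu <- sd_pop(x) / sy
    degenerate <- FALSE
  }
  structure(list(x = x, y = y, mu = mu, degenerate = degenerate),
            class = "chrom_pair")
}

#' Combine a chrominance pair into the pulse signal
#'
#' `rPPG(t) = x(t) - mu * y(t)` elementwise. A degenerate pair
#' (`sd(y) = 0`, `mu = 0`) yields `rPPG = x` with the no-signal flag
#' carried forward; heart-rate estimation reports no signal if the
#' resulting pulse is identically zero.
#'
#' @param pair A [chrom_project()] result.
#' @param fps Sampling rate, Hz.
#' @return A `pulse_signal`: list `samples`, `fps`, `no_signal`.
#' @export
chrom_pulse <- function(pair, fps) {
  stopifnot(inherits(pair, "chrom_pair"))
  stopifnot_scalar_pos(fps, "fps")
  structure(list(samples = pair$x - pair$mu * pair$y, fps = fps,
                 no_signal = pair$degenerate),
            class = "pulse_signal")
}

#' Spectral heart-rate estimate for one pulse window
#'
#' Applies a Hann taper, zero-pads to at least `2^15` points (spectral
#' grid spacing well below 0.5 bpm for ordinary frame rates), and takes
#' the frequency of the maximum power-spectrum peak restricted to the
#' pass band; `hr_bpm = 60 * f_hr` exactly. Ties break toward the lower
#' frequency. An identically-zero pulse yields a no-signal result
#' (`f_hr = NA`, quality 0).
#'
#' @param pulse A [chrom_pulse()] result.
#' @param band A [band_limits()]; the default 0.7-4 Hz band corresponds
#'   to 42-240 bpm.
#' @param window_start_s Start time carried into the result.
#' @return An `hr_estimate`: list `f_hr` (Hz), `hr_bpm`,
#'   `peak_power_fraction` (peak power / total in-band power, in
#'   `[0, 1]`), `window_start_s`, `no_signal`.
#' @export
estimate_hr <- function(pulse, band = band_limits(), window_start_s = 0) {
  stopifnot(inherits(pulse, "pulse_signal"))
  s <- pulse$samples
  n <- length(s)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (all(s == 0)) {
    return(structure(list(f_hr = NA_real_, hr_bpm = NA_real_,
                          peak_power_fraction = 0,
                          window_start_s = window_start_s,
                          no_signal = TRUE),
                     class = "hr_estimate"))
  }
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  tapered <- s * hann
  nfft <- max(2^15, 2^ceiling(log2(n)))
  padded <- c(tapered, rep(0, nfft - n))
  power <- Mod(fft(padded))^2
  freqs <- (seq_len(nfft) - 1) * pulse$fps / nfft
  inband <- which(freqs >= band$f_low & freqs <= band$f_high)
  if (length(inband) == 0L) {
    stop("pass band contains no spectral bins", call. = FALSE)
  }
  p <- power[inband]
  peak <- which.max(p)  # first maximum = lowest frequency on ties
  f_hr <- freqs[inband[peak]]
  structure(list(f_hr = f_hr, hr_bpm = 60 * f_hr,
                 peak_power_fraction = p[peak] / sum(p),
                 window_start_s = window_start_s,
                 no_signal = FALSE),
            class = "hr_estimate")
}
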