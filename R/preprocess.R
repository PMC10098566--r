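# Per-window signal conditioning: linear detrend, max-abs normalization,
# moving-average smoothing, 0.7-4 Hz band-pass — applied in that order to
# each channel before chrominance projection. 0.7-4 Hz corresponds to
# 42-240 beats per minute.
#
# "Third-order band-pass with ideal behavior" is read as a third-order
# Butterworth applied forward-backward (zero phase); an FFT brick-wall
# mode ("ideal") is available for comparison. No DSP package ships with
# this environment, so the filter design (Butterworth zpk prototype ->
# low-pass-to-band-pass transform -> bilinear transform) and the
# zero-phase filter (odd-extension padding + steady-state initial
# conditions) are implemented here; coefficients are test-pinned against
# an independent reference design.

#' Band limits for physiological heart rates
#'
#' @param f_low,f_high Pass band edges in Hz. The defaults 0.7 and 4.0 Hz
#'   correspond to 42 and 240 bpm.
#' @return A `band_limits` object.
#' @export
band_limits <- function(f_low = 0.7, f_high = 4.0) {
  if (!(f_low > 0 && f_high > f_low)) {
    stop("need 0 < f_low < f_high", call. = FALSE)
  }
  structure(list(f_low = f_low, f_high = f_high), class = "band_limits")
}

#' Remove the least-squares linear trend
#'
#' Subtracts the ordinary-least-squares line so the output's best-fit
#' slope and intercept are zero to numerical tolerance.
#'
#' @param x Numeric sequence, length >= 2.
#' @return Detrended sequence, same length.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to detrend", call. = FALSE)
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc^2)
  x - (mean(x) + slope * tc)
}

#' Normalize by the maximum absolute value
#'
#' For nonzero input the result's max-abs is exactly 1; an all-zero
#' input is returned unchanged (downstream heart-rate estimation flags
#' the no-signal window).
#'
#' @param x Numeric sequence, non-empty.
#' @return Normalized sequence.
#' @export
normalize_maxabs <- function(x) {
  if (length(x) == 0L) stop("empty sequence", call. = FALSE)
  m <- max(abs(x))
  if (m == 0) x else x / m
}

#' Centered moving-average smoothing
#'
#' A centered `w`-point mean with reflection padding at the edges
#' (`x[0]` mirrors to `x[2]`, i.e. the edge sample is not repeated);
#' output length equals input length.
#'
#' @param x Numeric sequence.
#' @param w Odd window length, `1 <= w <= length(x)`.
#' @return Smoothed sequence.
#' @export
smooth_moving_average <- function(x, w = 5L) {
  n <- length(x)
  if (!is_count(w) || w < 1 || w %% 2 == 0 || w > n) {
    stop("`w` must be an odd integer between 1 and length(x)", call. = FALSE)
  }
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  xp <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  cs <- cumsum(c(0, xp))
  (cs[(w + 1L):(n + w)] - cs[1:n]) / w
}

# --- Butterworth band-pass design ------------------------------------

# Polynomial with given roots (complex), leading coefficient 1.
poly_from_roots <- function(roots) {
  p <- 1 + 0i
  for (r in roots) p <- c(p, 0) - c(0, p * r)
  p
}

#' Digital Butterworth band-pass coefficients
#'
#' Designs an order-`order` analog Butterworth low-pass prototype,
#' transforms it to a band-pass (doubling the order), and discretizes by
#' the bilinear transform with frequency pre-warping. Matches the
#' standard reference design.
#'
#' @param order Prototype order (3 gives a 6th-order digital filter).
#' @param f_low,f_high Band edges in Hz.
#' @param fps Sampling rate in Hz; requires `f_high < fps / 2`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(order, f_low, f_high, fps) {
  if (!(f_low > 0 && f_high > f_low)) {
    stop("need 0 < f_low < f_high", call. = FALSE)
  }
  if (f_high >= fps / 2) {
    stop("f_high must be below the Nyquist frequency fps/2", call. = FALSE)
  }
  n <- as.integer(order)
  # analog prototype: poles on the unit circle's left half
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  gain <- 1
  # pre-warp band edges (bilinear with fs = 2)
  fs <- 2
  w1 <- 2 * fs * tan(pi * (f_low / (fps / 2)) / 2)
  w2 <- 2 * fs * tan(pi * (f_high / (fps / 2)) / 2)
  bw <- w2 - w1
  wo <- sqrt(w1 * w2)
  # low-pass -> band-pass: each pole splits in two; n zeros at s = 0
  pl <- p * bw / 2
  pbp <- c(pl + sqrt(pl^2 - wo^2), pl - sqrt(pl^2 - wo^2))
  zbp <- rep(0 + 0i, n)
  gain <- gain * bw^n
  # bilinear transform
  fs2 <- 2 * fs
  degree <- length(pbp) - length(zbp)
  zd <- (fs2 + zbp) / (fs2 - zbp)
  pd <- (fs2 + pbp) / (fs2 - pbp)
  gain <- gain * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  zd <- c(zd, rep(-1 + 0i, degree))
  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Direct-form II transposed difference equation with initial state.
iir_filter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, nf - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (nf > 2) {
      z[1:(nf - 2)] <- b[2:(nf - 1)] * x[i] + z[2:(nf - 1)] - a[2:(nf - 1)] * y[i]
    }
    z[nf - 1] <- b[nf] * x[i] - a[nf] * y[i]
  }
  y
}

# Steady-state initial filter state for a unit step (reference filtfilt
# initial conditions): solves (I - A) zi = B in companion form.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  A <- rbind(-a[2:nf], cbind(diag(nf - 2), rep(0, nf - 2)))
  B <- b[2:nf] - b[1] * a[2:nf]
  solve(diag(nf - 1) - t(A), B)
}

# Zero-phase (forward-backward) IIR filtering with odd-extension padding.
filtfilt_iir <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  nf <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 3 * (nf - 1)
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    left <- 2 * x[1] - x[(padlen + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  if (padlen > 0) y[(padlen + 1):(padlen + n)] else y
}

#' Band-pass filter a sequence
#'
#' Zero-phase application of a third-order Butterworth band-pass
#' (`method = "butterworth"`, the default) or an FFT brick-wall filter
#' (`method = "ideal"`): out-of-band components are strongly attenuated,
#' in-band components preserved without phase distortion.
#'
#' @param x Numeric sequence.
#' @param fps Sampling rate, Hz.
#' @param band A [band_limits()].
#' @param order Butterworth prototype order (default 3).
#' @param method `"butterworth"` or `"ideal"`.
#' @return Filtered sequence, same length.
#' @export
bandpass <- function(x, fps, band = band_limits(), order = 3,
                     method = c("butterworth", "ideal")) {
  method <- match.arg(method)
  if (band$f_high >= fps / 2) {
    stop("f_high must be below the Nyquist frequency fps/2", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (method == "ideal") {
    X <- fft(x)
    f <- (seq_len(n) - 1) * fps / n
    f <- pmin(f, fps - f)  # two-sided frequency magnitude
    keep <- f >= band$f_low & f <= band$f_high
    return(Re(fft(X * keep, inverse = TRUE)) / n)
  }
  co <- butter_bandpass(order, band$f_low, band$f_high, fps)
  # transients of the low edge (~fps/f_low samples) must fit the padding
  padlen <- min(n - 1, max(3 * (length(co$a) - 1), ceiling(3 * fps / band$f_low)))
  filtfilt_iir(co$b, co$a, x, padlen = padlen)
}

#' Condition one analysis window
#'
#' Applies, per channel and in order: linear detrend, normalization,
#' moving-average smoothing, band-pass. Each stage is
#' length-preserving.
#'
#' Two normalization readings are implemented. `"mean"` (the default)
#' divides each detrended channel by that channel's temporal mean
#' intensity, as in the original chrominance method: relative pulsatile
#' amplitudes between channels are preserved, which the projection
#' needs — under per-channel amplitude equalization a noise-free pulse
#' that modulates all channels proportionally becomes identical across
#' channels and falls into the projection's achromatic null space.
#' `"maxabs"` rescales each channel to unit maximum absolute value
#' (channel values in `[-1, 1]`), the literal per-channel normalization
#' reading; it is retained for comparison.
#'
#' @param window An `rgb_window` from [window_stream()].
#' @param band A [band_limits()].
#' @param smooth_w Odd moving-average length (samples), default 5.
#' @param order Band-pass prototype order, default 3.
#' @param method Filter method, `"butterworth"` or `"ideal"`.
#' @param normalization `"mean"` or `"maxabs"` (see Details).
#' @return A `conditioned_window`: list `r`, `g`, `b`, `fps`, `start_s`.
#' @export
condition_window <- function(window, band = band_limits(), smooth_w = 5L,
                             order = 3, method = "butterworth",
                             normalization = c("mean", "maxabs")) {
  stopifnot(inherits(window, "rgb_window"))
  normalization <- match.arg(normalization)
  cond <- function(x) {
    d <- detrend_linear(x)
    nrm <- if (normalization == "mean") {
      m <- mean(x)
      if (m == 0) d else d / m
    } else {
      normalize_maxabs(d)
    }
    bandpass(smooth_moving_average(nrm, smooth_w),
             window$fps, band, order, method)
  }
  structure(list(r = cond(window$r), g = cond(window$g), b = cond(window$b),
                 fps = window$fps, start_s = window$start_s),
            class = "conditioned_window")
}
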