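# Spatial averaging of ROI pixels into RGB traces, and segmentation of a
# trace into overlapping analysis windows (default 30 s long, 1 s slide:
# one heart-rate estimate per second after the first 30 s).

#' Construct an RGB trace
#'
#' A time-indexed per-channel mean-color sequence; sample `i` corresponds
#' to time `(i - 1) / fps` seconds. `valid` marks frames on which a ROI
#' was available (face found).
#'
#' @param r,g,b Numeric sequences of per-frame channel means.
#' @param fps Frame rate.
#' @param valid Logical sequence, recycled from TRUE.
#' @return An `rgb_trace` object.
#' @export
rgb_trace <- function(r, g, b, fps, valid = TRUE) {
  n <- length(r)
  if (length(g) != n || length(b) != n) {
    stop("channel sequences must have equal length", call. = FALSE)
  }
  stopifnot_scalar_pos(fps, "fps")
  valid <- rep_len(valid, n)
  structure(list(r = r, g = g, b = b, fps = fps, valid = valid),
            class = "rgb_trace")
}

#' @export
length.rgb_trace <- function(x) length(x$r)

#' Mean ROI color of one frame
#'
#' Arithmetic mean of each channel over the mask pixels. An empty mask
#' yields an invalid sample (`NA` color, `valid = FALSE`) rather than an
#' error; downstream windowing drops windows containing invalid samples.
#'
#' @param frame `height x width x 3` numeric array.
#' @param mask A logical matrix or a `roi_mask` from [forehead_mask()].
#' @return A list with `rgb` (length-3 numeric) and `valid` (logical).
#' @export
extract_mean_rgb <- function(frame, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!is.logical(m) || !identical(dim(m), dim(frame)[1:2])) {
    stop("mask must be a logical matrix matching the frame", call. = FALSE)
  }
  if (!any(m)) {
    return(list(rgb = c(NA_real_, NA_real_, NA_real_), valid = FALSE))
  }
  list(rgb = c(mean(frame[, , 1][m]), mean(frame[, , 2][m]),
               mean(frame[, , 3][m])),
       valid = TRUE)
}

#' Segment a trace into overlapping analysis windows
#'
#' Window `k` (k = 0, 1, ...) covers samples
#' `[k * round(fps * slide_s), k * round(fps * slide_s) + round(fps *
#' window_s))` (0-based), i.e. it starts at `k * slide_s` seconds. Only
#' complete windows are emitted, and windows containing invalid samples
#' are dropped (conservative: no interpolation) and counted in the
#' `n_dropped` attribute.
#'
#' @param trace An [rgb_trace()].
#' @param window_s Window length, seconds (default 30).
#' @param slide_s Slide between consecutive windows, seconds (default 1).
#' @return A list of `rgb_window` objects (possibly empty), each a list
#'   `start_s`, `duration_s`, `r`, `g`, `b`, `fps`.
#' @export
window_stream <- function(trace, window_s = 30, slide_s = 1) {
  stopifnot(inherits(trace, "rgb_trace"))
  stopifnot_scalar_pos(window_s, "window_s")
  stopifnot_scalar_pos(slide_s, "slide_s")
  n <- length(trace)
  wlen <- round(trace$fps * window_s)
  step <- round(trace$fps * slide_s)
  if (wlen < 1 || step < 1) {
    stop("window_s and slide_s must cover at least one sample", call. = FALSE)
  }
  out <- list()
  dropped <- 0L
  k <- 0L
  repeat {
    a <- k * step + 1L
    b <- a + wlen - 1L
    if (b > n) break
    if (all(trace$valid[a:b])) {
      out[[length(out) + 1L]] <- structure(
        list(start_s = (a - 1L) / trace$fps, duration_s = window_s,
             r = trace$r[a:b], g = trace$g[a:b], b = trace$b[a:b],
             fps = trace$fps),
        class = "rgb_window")
    } else {
      dropped <- dropped + 1L
    }
    k <- k + 1L
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Export a trace as a CSV (`time_s,r,g,b,valid`)
#'
#' @param trace An [rgb_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  n <- length(trace)
  df <- data.frame(time_s = (seq_len(n) - 1) / trace$fps,
                   r = trace$r, g = trace$g, b = trace$b,
                   valid = trace$valid)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
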