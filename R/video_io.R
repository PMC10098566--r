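# Frame I/O: a uniform frame-source abstraction over video files.
#
# Container: a concatenated stream of binary P6 PPM images (lossless;
# the image2pipe convention understood by ffmpeg). Lossy codecs would
# destroy the sub-intensity color modulations that carry the pulse, so
# lossless storage is mandatory for fixtures. Frame rate, which PPM does
# not carry, lives in a JSON sidecar `<path>.json` ({"fps": ...}) or is
# supplied by the caller. Internal channel order is fixed to (R, G, B):
# the chrominance projection is channel-asymmetric, so a silent B/R swap
# would corrupt results; readers convert at the boundary (PPM is already
# RGB).

#' Write frames as a lossless PPM video stream
#'
#' @param frames List of `height x width x 3` integer arrays (8-bit RGB).
#' @param path Output file path.
#' @param fps Nominal frame rate, written to the `<path>.json` sidecar.
#' @return Invisibly, `path`.
#' @export
write_video <- function(frames, path, fps = 30) {
  stopifnot_scalar_pos(fps, "fps")
  con <- file(path, "wb")
  on.exit(close(con))
  for (fr in frames) {
    d <- dim(fr)
    if (length(d) != 3L || d[3] != 3L) {
      stop("each frame must be a height x width x 3 array", call. = FALSE)
    }
    writeBin(charToRaw(sprintf("P6\n%d %d\n255\n", d[2], d[1])), con)
    # PPM is row-major, pixel-interleaved RGB; R arrays are column-major.
    px <- aperm(fr, c(3, 2, 1))  # (channel, col, row) -> interleave fastest
    writeBin(as.raw(as.integer(px)), con)
  }
  jsonlite::write_json(list(fps = fps), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

scan_ppm_stream <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  offsets <- integer(0)
  widths <- integer(0)
  heights <- integer(0)
  pos <- 0
  truncated <- FALSE
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) return(NULL)
      pos <<- pos + 1L
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L) return(NULL)
          pos <<- pos + 1L
          if (ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  while (pos < sz) {
    magic <- read_token()
    if (is.null(magic)) break
    if (magic != "P6") {
      stop(sprintf("not a P6 PPM stream: '%s' at byte %d in %s",
                   magic, pos, path), call. = FALSE)
    }
    w <- as.integer(read_token())
    h <- as.integer(read_token())
    maxval <- as.integer(read_token())
    if (is.na(w) || is.na(h) || is.na(maxval) || maxval != 255L) {
      stop(sprintf("bad PPM header in %s", path), call. = FALSE)
    }
    nbytes <- 3 * w * h
    if (pos + nbytes > sz) {
      truncated <- TRUE
      break
    }
    offsets <- c(offsets, pos)
    widths <- c(widths, w)
    heights <- c(heights, h)
    seek(con, nbytes, origin = "current")
    pos <- pos + nbytes
  }
  list(offsets = offsets, widths = widths, heights = heights,
       truncated = truncated)
}

#' Open a video file as a frame source
#'
#' @param uri Path to a PPM-stream video file. Integer camera device ids
#'   are part of the interface but not supported by this build.
#' @param requested_resolution Optional `c(width, height)`; frames are
#'   rescaled to it on read (nearest-neighbor).
#' @param fps Frame rate override; by default taken from the `<uri>.json`
#'   sidecar, falling back to 30.
#' @return A `frame_source` object with fields `fps`, `width`, `height`,
#'   `n_frames`.
#' @export
open_source <- function(uri, requested_resolution = NULL, fps = NULL) {
  if (is.numeric(uri)) {
    stop("camera capture is not supported in this build; ",
         "pass a video file path", call. = FALSE)
  }
  if (!file.exists(uri)) {
    stop(sprintf("cannot open video source: '%s' (no such file)", uri),
         call. = FALSE)
  }
  idx <- scan_ppm_stream(uri)
  if (idx$truncated) {
    warning(sprintf("truncated trailing frame in %s skipped", uri),
            call. = FALSE)
  }
  if (is.null(fps)) {
    sidecar <- paste0(uri, ".json")
    fps <- if (file.exists(sidecar)) {
      as.numeric(jsonlite::read_json(sidecar)$fps)
    } else {
      30
    }
  }
  stopifnot_scalar_pos(fps, "fps")
  native_w <- if (length(idx$widths)) idx$widths[1] else 0L
  native_h <- if (length(idx$heights)) idx$heights[1] else 0L
  out_w <- native_w
  out_h <- native_h
  if (!is.null(requested_resolution)) {
    stopifnot(length(requested_resolution) == 2L)
    out_w <- as.integer(requested_resolution[1])
    out_h <- as.integer(requested_resolution[2])
    if (out_w <= 0 || out_h <= 0) {
      stop("requested resolution must be positive", call. = FALSE)
    }
  }
  structure(
    list(path = uri, fps = fps, width = out_w, height = out_h,
         native_width = native_w, native_height = native_h,
         n_frames = length(idx$offsets), index = idx,
         color_order = c("R", "G", "B")),
    class = "frame_source"
  )
}

resize_nearest <- function(frame, out_w, out_h) {
  d <- dim(frame)
  if (d[1] == out_h && d[2] == out_w) return(frame)
  rows <- pmin(d[1], floor((seq_len(out_h) - 0.5) * d[1] / out_h) + 1L)
  cols <- pmin(d[2], floor((seq_len(out_w) - 0.5) * d[2] / out_w) + 1L)
  frame[rows, cols, , drop = FALSE]
}

read_frame_at <- function(source, i) {
  idx <- source$index
  con <- file(source$path, "rb")
  on.exit(close(con))
  seek(con, idx$offsets[i])
  w <- idx$widths[i]
  h <- idx$heights[i]
  bytes <- readBin(con, "raw", 3 * w * h)
  px <- as.integer(bytes)
  fr <- aperm(array(px, dim = c(3, w, h)), c(3, 2, 1))
  resize_nearest(fr, source$width, source$height)
}

#' Read all frames of a source
#'
#' Timestamps are `frame_index / fps` (uniform nominal sampling; the
#' windowing stages assume it).
#'
#' @param source A [open_source()] result.
#' @return A list with `timestamps` (seconds) and `frames` (list of
#'   integer arrays).
#' @export
read_frames <- function(source) {
  stopifnot(inherits(source, "frame_source"))
  n <- source$n_frames
  frames <- vector("list", n)
  if (n > 0) {
    con <- file(source$path, "rb")
    on.exit(close(con))
    for (i in seq_len(n)) {
      seek(con, source$index$offsets[i])
      w <- source$index$widths[i]
      h <- source$index$heights[i]
      bytes <- readBin(con, "raw", 3 * w * h)
      fr <- aperm(array(as.integer(bytes), dim = c(3, w, h)), c(3, 2, 1))
      frames[[i]] <- resize_nearest(fr, source$width, source$height)
    }
  }
  list(timestamps = (seq_len(n) - 1) / source$fps, frames = frames)
}

#' Apply a function to each frame of a source without loading all frames
#'
#' @param source A [open_source()] result.
#' @param f Function of `(timestamp_s, frame)`.
#' @return A list of `f` results, one per frame.
#' @export
fold_frames <- function(source, f) {
  stopifnot(inherits(source, "frame_source"))
  n <- source$n_frames
  out <- vector("list", n)
  if (n == 0) return(out)
  con <- file(source$path, "rb")
  on.exit(close(con))
  for (i in seq_len(n)) {
    seek(con, source$index$offsets[i])
    w <- source$index$widths[i]
    h <- source$index$heights[i]
    bytes <- readBin(con, "raw", 3 * w * h)
    fr <- aperm(array(as.integer(bytes), dim = c(3, w, h)), c(3, 2, 1))
    fr <- resize_nearest(fr, source$width, source$height)
    out[[i]] <- f((i - 1) / source$fps, fr)
  }
  out
}
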