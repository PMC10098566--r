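# Pipeline orchestration: source -> ROI -> (enhance) -> trace ->
# windows -> conditioning -> chrominance pulse -> spectral HR ->
# (evaluation), as a configured, logged run. Per-stage wall-clock
# timings are informational only.

#' Pipeline run configuration
#'
#' @param source Path to a video file (see [open_source()]).
#' @param fps Frame-rate override (default: sidecar, else 30).
#' @param resolution Optional `c(width, height)` to rescale frames.
#' @param window_s,slide_s Analysis window length and slide, seconds
#'   (defaults 30 and 1: one estimate per second after the first 30 s).
#' @param band `c(f_low, f_high)` pass band in Hz, default `c(0.7, 4)`.
#' @param enhance Enable the low-light double-plateau equalization stage
#'   (default `FALSE`; disabled means the identity mapping).
#' @param smooth_w Moving-average length, samples.
#' @param filter `"butterworth"` or `"ideal"`.
#' @param normalization Channel normalization, `"mean"` (default) or
#'   `"maxabs"`; see [condition_window()].
#' @param order Band-pass prototype order.
#' @param roi Declared ROI: a `roi.json` path or a list `x`, `y`, `w`,
#'   `h`. When given, the fixture backend is used; otherwise the patch
#'   detector.
#' @param cs A [cs_config()] for the enhancement optimizer.
#' @param truth Optional ground-truth CSV path (`time_s,hr_bpm`).
#' @param tol_bpm Accuracy tolerance for evaluation (default 3).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return An `rppg_config` object.
#' @export
rppg_config <- function(source, fps = NULL, resolution = NULL,
                        window_s = 30, slide_s = 1, band = c(0.7, 4),
                        enhance = FALSE, smooth_w = 5L,
                        filter = "butterworth", order = 3,
                        normalization = "mean",
                        roi = NULL, cs = cs_config(),
                        truth = NULL, tol_bpm = 3, out_dir = NULL) {
  structure(list(source = source, fps = fps, resolution = resolution,
                 window_s = window_s, slide_s = slide_s,
                 band = band_limits(band[1], band[2]),
                 enhance = isTRUE(enhance), smooth_w = smooth_w,
                 filter = filter, order = order,
                 normalization = normalization, roi = roi, cs = cs,
                 truth = truth, tol_bpm = tol_bpm, out_dir = out_dir),
            class = "rppg_config")
}

resolve_backend <- function(config) {
  if (is.null(config$roi)) return(roi_backend_patch())
  box <- config$roi
  if (is.character(box)) box <- jsonlite::read_json(box)
  roi_backend_fixture(list(x = as.integer(box$x), y = as.integer(box$y),
                           w = as.integer(box$w), h = as.integer(box$h)))
}

#' Run the full heart-rate estimation pipeline
#'
#' Streams frames from the source, locates the forehead ROI per frame
#' (when detection fails the last valid mask is reused for at most `fps`
#' consecutive frames, after which samples are marked invalid and their
#' windows dropped), optionally enhances the ROI, averages it into an
#' RGB trace, and produces one spectral heart-rate estimate per emitted
#' window. When a ground-truth CSV is configured the estimates are also
#' scored with the `|error| < tol` criterion.
#'
#' @param config An [rppg_config()].
#' @return A list with `estimates` (data.frame `window_start_s`,
#'   `f_hr_hz`, `hr_bpm`, `quality`), `trace` (the [rgb_trace()]),
#'   `report` (an `eval_report` or `NULL`) and `timings_s` (named,
#'   informational).
#' @export
rppg_run <- function(config) {
  stopifnot(inherits(config, "rppg_config"))
  timings <- c(face_detection = 0, signal_extraction = 0,
               signal_estimation = 0)
  src <- open_source(config$source, requested_resolution = config$resolution,
                     fps = config$fps)
  backend <- resolve_backend(config)
  plateaus <- NULL
  last_mask <- NULL
  stale <- 0L
  max_stale <- ceiling(src$fps)
  t0 <- proc.time()[3]
  samples <- fold_frames(src, function(ts, frame) {
    box <- detect_face(frame, backend)
    mask <- NULL
    if (!is.null(box)) {
      lm <- extract_landmarks(frame, box, backend)
      rm <- forehead_mask(lm, dim(frame)[1:2])
      if (rm$area > 0) mask <- rm$mask
    }
    if (is.null(mask)) {
      if (!is.null(last_mask) && stale < max_stale) {
        mask <- last_mask
        stale <<- stale + 1L
      }
    } else {
      last_mask <<- mask
      stale <<- 0L
    }
    if (is.null(mask)) return(list(rgb = rep(NA_real_, 3), valid = FALSE))
    if (config$enhance) {
      px <- cbind(frame[, , 1][mask], frame[, , 2][mask], frame[, , 3][mask])
      y <- pmin(pmax(as.integer(round(luminance(px[, 1], px[, 2], px[, 3]))),
                     0L), 255L)
      hist <- tabulate(y + 1L, nbins = 256L)
      if (is.null(plateaus)) {
        lev <- segment_histogram(hist)
        plateaus <<- optimize_plateaus(hist, lev, config$cs)
      }
      enh <- apply_double_plateau_equalization(px, plateaus)
      list(rgb = colMeans(enh$pixels), valid = TRUE)
    } else {
      extract_mean_rgb(frame, mask)
    }
  })
  timings["face_detection"] <- proc.time()[3] - t0
  t0 <- proc.time()[3]
  rgb <- t(vapply(samples, `[[`, numeric(3), "rgb"))
  valid <- vapply(samples, `[[`, TRUE, "valid")
  if (!any(valid)) {
    stop("no valid ROI found in the whole stream; no estimate possible",
         call. = FALSE)
  }
  trace <- rgb_trace(rgb[, 1], rgb[, 2], rgb[, 3], fps = src$fps,
                     valid = valid)
  windows <- window_stream(trace, config$window_s, config$slide_s)
  timings["signal_extraction"] <- proc.time()[3] - t0
  t0 <- proc.time()[3]
  ests <- lapply(windows, function(w) {
    cw <- condition_window(w, config$band, config$smooth_w, config$order,
                           config$filter, config$normalization)
    pulse <- chrom_pulse(chrom_project(cw), fps = w$fps)
    estimate_hr(pulse, config$band, window_start_s = w$start_s)
  })
  timings["signal_estimation"] <- proc.time()[3] - t0
  estimates <- data.frame(
    window_start_s = vapply(ests, `[[`, 0, "window_start_s"),
    f_hr_hz = vapply(ests, `[[`, 0, "f_hr"),
    hr_bpm = vapply(ests, `[[`, 0, "hr_bpm"),
    quality = vapply(ests, `[[`, 0, "peak_power_fraction"))
  report <- NULL
  if (!is.null(config$truth)) {
    gt <- read_ground_truth(config$truth)
    report <- score_estimates(estimates, gt, tol_bpm = config$tol_bpm,
                              window_s = config$window_s)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(estimates, file.path(config$out_dir, "estimates.csv"),
              row.names = FALSE, quote = FALSE)
    cfg <- config
    cfg$band <- unclass(cfg$band)
    cfg$cs <- unclass(cfg$cs)
    jsonlite::write_json(unclass(cfg), file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, null = "null")
    if (!is.null(report)) {
      jsonlite::write_json(
        list(n_windows = report$n_windows,
             accuracy_pct = report$accuracy_pct,
             mae_bpm = report$mae_bpm, rmse_bpm = report$rmse_bpm),
        file.path(config$out_dir, "report.json"), auto_unbox = TRUE)
      write.csv(report$per_window,
                file.path(config$out_dir, "report_windows.csv"),
                row.names = FALSE, quote = FALSE)
    }
  }
  message(sprintf(
    "stages [s]: face detection %.2f | signal extraction %.2f | signal estimation %.2f",
    timings["face_detection"], timings["signal_extraction"],
    timings["signal_estimation"]))
  list(estimates = estimates, trace = trace, report = report,
       timings_s = timings)
}
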