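# Scoring of heart-rate estimates against a ground-truth series with the
# |error| < 3 bpm accuracy criterion ("falls below": strict inequality),
# plus mean-absolute and root-mean-square error summaries.

#' Construct a ground-truth heart-rate series
#'
#' @param timestamps Strictly increasing times, seconds.
#' @param hr_bpm Heart-rate values, beats per minute, same length.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(timestamps, hr_bpm) {
  if (length(timestamps) != length(hr_bpm)) {
    stop("timestamps and hr_bpm must have equal length", call. = FALSE)
  }
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(list(timestamps = timestamps, hr_bpm = hr_bpm),
            class = "ground_truth")
}

#' Read a ground-truth CSV (`time_s,hr_bpm` header)
#'
#' @param path CSV path.
#' @return A [ground_truth()] object.
#' @export
read_ground_truth <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "hr_bpm") %in% names(df))) {
    stop(sprintf("'%s' must have columns time_s,hr_bpm", path),
         call. = FALSE)
  }
  ground_truth(df$time_s, df$hr_bpm)
}

#' Reference heart rate for one analysis window
#'
#' The mean of ground-truth samples whose timestamps fall in
#' `[window_start_s, window_start_s + window_s)`. A window with no
#' ground-truth samples is excluded (returns `NA`) and logged by the
#' caller.
#'
#' @param gt A [ground_truth()] object.
#' @param window_start_s Window start, seconds.
#' @param window_s Window length, seconds.
#' @return Mean bpm, or `NA` when the interval holds no samples.
#' @export
align_ground_truth <- function(gt, window_start_s, window_s) {
  stopifnot(inherits(gt, "ground_truth"))
  sel <- gt$timestamps >= window_start_s &
         gt$timestamps < window_start_s + window_s
  if (!any(sel)) return(NA_real_)
  mean(gt$hr_bpm[sel])
}

#' Score heart-rate estimates against ground truth
#'
#' A window is a hit when `|estimate - truth| < tol_bpm` (strict);
#' accuracy is the hit percentage over matchable windows. MAE and RMSE
#' are computed over the same windows. Windows with a no-signal estimate
#' or no overlapping ground truth are excluded.
#'
#' @param estimates A data.frame with columns `window_start_s` and
#'   `hr_bpm` (as produced by [rppg_run()]), or a list of `hr_estimate`
#'   objects.
#' @param gt A [ground_truth()] object.
#' @param tol_bpm Accuracy tolerance in bpm (default 3).
#' @param window_s Window length used for alignment (default 30).
#' @return An `eval_report`: list `n_windows`, `accuracy_pct`,
#'   `mae_bpm`, `rmse_bpm`, `per_window` (data.frame with
#'   `window_start_s`, `hr_est`, `hr_gt`, `abs_err`, `hit`).
#' @export
score_estimates <- function(estimates, gt, tol_bpm = 3, window_s = 30) {
  stopifnot(inherits(gt, "ground_truth"))
  stopifnot_scalar_pos(tol_bpm, "tol_bpm")
  if (is.list(estimates) && !is.data.frame(estimates) &&
      length(estimates) && inherits(estimates[[1]], "hr_estimate")) {
    estimates <- data.frame(
      window_start_s = vapply(estimates, `[[`, 0, "window_start_s"),
      hr_bpm = vapply(estimates, `[[`, 0, "hr_bpm"))
  }
  keep <- !is.na(estimates$hr_bpm)
  est <- estimates[keep, , drop = FALSE]
  hr_gt <- vapply(est$window_start_s, align_ground_truth, 0,
                  gt = gt, window_s = window_s)
  matched <- !is.na(hr_gt)
  if (!any(matched)) {
    stop("no estimate window overlaps the ground-truth series",
         call. = FALSE)
  }
  est <- est[matched, , drop = FALSE]
  hr_gt <- hr_gt[matched]
  abs_err <- abs(est$hr_bpm - hr_gt)
  hit <- abs_err < tol_bpm
  per_window <- data.frame(window_start_s = est$window_start_s,
                           hr_est = est$hr_bpm, hr_gt = hr_gt,
                           abs_err = abs_err, hit = hit)
  structure(list(n_windows = nrow(per_window),
                 accuracy_pct = 100 * mean(hit),
                 mae_bpm = mean(abs_err),
                 rmse_bpm = sqrt(mean(abs_err^2)),
                 per_window = per_window),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "HR evaluation over %d windows: accuracy (|err| < tol) %.2f%%, MAE %.3f bpm, RMSE %.3f bpm\n",
    x$n_windows, x$accuracy_pct, x$mae_bpm, x$rmse_bpm))
  invisible(x)
}
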