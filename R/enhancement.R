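# Optional low-light ROI enhancement: double-plateau histogram
# equalization with plateau limits chosen by a cuckoo-search optimizer.
#
# The luminance histogram is split at an Otsu threshold into two
# sub-histograms; each is clipped between a lower and an upper plateau
# (limiting noise amplification and preserving sparse detail) before a
# per-segment equalization mapping is built. The plateau pair is chosen
# to maximize the sum of Shannon entropies of the two clipped-equalized
# sub-histograms — a standard contrast/detail balance objective; the
# optimizer is a seeded cuckoo search with Levy flights.
#
# Enhancement operates on luminance only: the pulse information is
# chromatic, so per-pixel color differences (R-G, G-B) are preserved
# exactly by shifting all channels by the same luminance delta (up to
# 8-bit clipping). The stage is OFF by default in the pipeline —
# under adequate light the minimal measurement chain is preferable.

#' Otsu segmentation level of a 256-bin histogram
#'
#' Maximizes the between-class variance over all thresholds `L`, where
#' class 0 holds bins `0..L` and class 1 bins `L+1..255` (0-based bin
#' values). Tie rule: when several levels maximize the variance (a
#' plateau, e.g. between two separated modes), the floor of the mean of
#' the tied levels — the plateau midpoint — is returned, centering the
#' threshold between the modes. A histogram with all its mass in one bin
#' returns that bin.
#'
#' @param hist Numeric vector of 256 nonnegative bin counts, at least one
#'   nonzero.
#' @return Integer level in `0..255`.
#' @export
segment_histogram <- function(hist) {
  if (length(hist) != 256L || all(hist == 0) || any(hist < 0)) {
    stop("`hist` must be 256 nonnegative counts with at least one nonzero",
         call. = FALSE)
  }
  nz <- which(hist > 0)
  if (length(nz) == 1L) return(nz - 1L)
  p <- hist / sum(hist)
  v <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * v)
  mt <- m0[256]
  # between-class variance sigma_b^2(L) = (mt*w0 - m0)^2 / (w0*(1-w0))
  denom <- w0 * (1 - w0)
  sigma_b <- ifelse(denom > 0, (mt * w0 - m0)^2 / denom, -Inf)
  sigma_b <- sigma_b[1:255]  # L = 255 leaves class 1 empty
  tied <- which(sigma_b >= max(sigma_b) - 1e-9 * max(1, max(sigma_b)))
  as.integer(floor(mean(tied))) - 1L
}

clip_subhist <- function(h, lower, upper) {
  h <- pmin(h, upper)
  nz <- h > 0
  h[nz] <- pmax(h[nz], lower)
  h
}

shannon_entropy <- function(h) {
  s <- sum(h)
  if (s <= 0) return(0)
  p <- h[h > 0] / s
  -sum(p * log2(p))
}

#' Double-plateau objective: entropy sum of the clipped sub-histograms
#'
#' @param hist 256-bin histogram.
#' @param level Segmentation level from [segment_histogram()].
#' @param lower,upper Plateau limits, `0 <= lower < upper`.
#' @return The sum of Shannon entropies (bits) of the two clipped
#'   sub-histograms.
#' @export
plateau_objective <- function(hist, level, lower, upper) {
  if (lower >= upper) return(-Inf)
  h1 <- clip_subhist(hist[1:(level + 1)], lower, upper)
  h2 <- if (level < 255) clip_subhist(hist[(level + 2):256], lower, upper) else numeric(0)
  shannon_entropy(h1) + shannon_entropy(h2)
}

#' Construct plateau parameters directly
#'
#' @param lower_plateau,upper_plateau Integer plateau limits,
#'   `0 <= lower < upper`.
#' @param segmentation_level Intensity bin separating the sub-histograms.
#' @return A `plateau_params` object.
#' @export
plateau_params <- function(lower_plateau, upper_plateau, segmentation_level) {
  if (lower_plateau < 0 || lower_plateau >= upper_plateau) {
    stop("need 0 <= lower_plateau < upper_plateau", call. = FALSE)
  }
  if (segmentation_level < 0 || segmentation_level > 255) {
    stop("segmentation_level must be in 0..255", call. = FALSE)
  }
  structure(list(lower_plateau = as.integer(lower_plateau),
                 upper_plateau = as.integer(upper_plateau),
                 segmentation_level = as.integer(segmentation_level),
                 objective = NA_real_),
            class = "plateau_params")
}

#' Cuckoo-search configuration
#'
#' @param n_nests Population size.
#' @param pa Abandonment probability per generation.
#' @param iterations Number of generations; 0 returns the best initial
#'   nest.
#' @param seed RNG seed; the search is reproducible from it.
#' @return A `cs_config` object.
#' @export
cs_config <- function(n_nests = 15, pa = 0.25, iterations = 50, seed = 1L) {
  stopifnot(n_nests >= 1, pa >= 0, pa <= 1, iterations >= 0)
  structure(list(n_nests = as.integer(n_nests), pa = pa,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "cs_config")
}

# Mantegna Levy step, beta = 1.5 (the customary cuckoo-search flight).
levy_step <- function(n, beta = 1.5) {
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
            (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- rnorm(n, 0, sigma)
  v <- rnorm(n)
  u / abs(v)^(1 / beta)
}

#' Choose plateau limits by cuckoo search
#'
#' Maximizes [plateau_objective()] over integer plateau pairs
#' `(lower, upper)` with `0 <= lower < upper <= max(hist)`. Elitism
#' guarantees the result is never worse than the best initial nest;
#' `iterations = 0` returns exactly that best initial candidate. An
#' optional discrete `candidates` matrix restricts the search to the
#' given `(lower, upper)` rows (candidate sets no larger than the
#' population are evaluated exhaustively).
#'
#' @param hist 256-bin histogram.
#' @param level Segmentation level.
#' @param config A [cs_config()].
#' @param candidates Optional 2-column matrix of allowed
#'   `(lower, upper)` pairs.
#' @return A `plateau_params` object: list `lower_plateau`,
#'   `upper_plateau`, `segmentation_level`, `objective`.
#' @export
optimize_plateaus <- function(hist, level, config = cs_config(),
                              candidates = NULL) {
  stopifnot(inherits(config, "cs_config"))
  obj <- function(cand) plateau_objective(hist, level, cand[1], cand[2])
  hmax <- max(hist)
  result <- with_seed(config$seed, {
    if (!is.null(candidates)) {
      candidates <- as.matrix(candidates)
      fit <- apply(candidates, 1, obj)
      best <- candidates[which.max(fit), ]
      list(cand = best, fit = max(fit))
    } else {
      lo_max <- max(1, hmax)
      snap <- function(x) {
        x[1] <- round(min(max(x[1], 0), lo_max - 1))
        x[2] <- round(min(max(x[2], x[1] + 1), lo_max))
        x
      }
      nests <- lapply(seq_len(config$n_nests), function(i) {
        snap(sort(runif(2, 0, lo_max)))
      })
      fit <- vapply(nests, obj, 0)
      bi <- which.max(fit)
      best <- nests[[bi]]; bestf <- fit[bi]
      if (config$iterations > 0) {
        for (it in seq_len(config$iterations)) {
          for (i in seq_len(config$n_nests)) {
            step <- 0.01 * levy_step(2) * (nests[[i]] - best)
            new <- snap(nests[[i]] + step * lo_max / 255)
            f <- obj(new)
            j <- sample.int(config$n_nests, 1)
            if (f > fit[j]) {
              nests[[j]] <- new; fit[j] <- f
            }
          }
          # abandon a fraction pa of the worst nests
          nab <- floor(config$pa * config$n_nests)
          if (nab > 0) {
            worst <- order(fit)[seq_len(nab)]
            for (j in worst) {
              nests[[j]] <- snap(sort(runif(2, 0, lo_max)))
              fit[j] <- obj(nests[[j]])
            }
          }
          bi <- which.max(fit)
          if (fit[bi] > bestf) {
            best <- nests[[bi]]; bestf <- fit[bi]  # elitism
          }
        }
      }
      list(cand = best, fit = bestf)
    }
  })
  structure(list(lower_plateau = as.integer(result$cand[1]),
                 upper_plateau = as.integer(result$cand[2]),
                 segmentation_level = as.integer(level),
                 objective = result$fit),
            class = "plateau_params")
}

# Per-segment equalization mapping for bin values lo..hi of a clipped
# sub-histogram: m(i) = lo + round((hi - lo) * cdf(i)).
segment_mapping <- function(h, lo, hi) {
  s <- sum(h)
  if (s <= 0) return(lo:hi)  # empty segment: identity
  cdf <- cumsum(h) / s
  as.integer(lo + round((hi - lo) * cdf))
}

#' Apply double-plateau histogram equalization to ROI pixels
#'
#' Builds the 256-entry luminance mapping (per-segment equalization of
#' the plateau-clipped sub-histograms; monotone nondecreasing by
#' construction) and applies it by shifting each pixel's three channels
#' by the same luminance delta, preserving per-pixel color differences
#' up to 8-bit clipping.
#'
#' @param pixels An `n x 3` integer matrix of ROI pixels (R, G, B) or a
#'   `height x width x 3` array.
#' @param params A `plateau_params` from [optimize_plateaus()]. With
#'   `lower_plateau = 0` and `upper_plateau >= max(hist)` the mapping is
#'   plain per-segment histogram equalization.
#' @return An `enhance_result`: list with `mapping` (256 integer values,
#'   index = luminance 0..255) and `pixels` (same shape as the input).
#' @export
apply_double_plateau_equalization <- function(pixels, params) {
  stopifnot(inherits(params, "plateau_params"))
  shape <- dim(pixels)
  px <- if (length(shape) == 3L) {
    cbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
          as.vector(pixels[, , 3]))
  } else {
    as.matrix(pixels)
  }
  y <- pmin(pmax(as.integer(round(luminance(px[, 1], px[, 2], px[, 3]))), 0L), 255L)
  hist <- tabulate(y + 1L, nbins = 256L)
  L <- params$segmentation_level
  h1 <- clip_subhist(hist[1:(L + 1)], params$lower_plateau, params$upper_plateau)
  m1 <- segment_mapping(h1, 0L, L)
  mapping <- m1
  if (L < 255) {
    h2 <- clip_subhist(hist[(L + 2):256], params$lower_plateau,
                       params$upper_plateau)
    m2 <- segment_mapping(h2, L + 1L, 255L)
    mapping <- c(m1, m2)
  }
  delta <- mapping[y + 1L] - y
  out <- clip8(px + delta)
  if (length(shape) == 3L) {
    out <- array(out, dim = shape)
  }
  structure(list(mapping = mapping, pixels = out), class = "enhance_result")
}

#' The identity luminance mapping (enhancement disabled)
#'
#' @return Integer vector `0:255`.
#' @export
identity_mapping <- function() 0:255
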