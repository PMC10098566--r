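# Independent oracles and small fixture builders shared across tests.
# Each oracle is a naive/brute-force formulation, deliberately separate
# from the implementation path it checks.

# Dominant non-DC frequency of a sequence via a direct DFT argmax.
oracle_peak_freq <- function(x, fps) {
  n <- length(x)
  amp <- Mod(fft(x))[2:floor(n / 2)]
  (which.max(amp)) * fps / n  # index k (1-based after dropping DC) -> k/n*fps
}

# Closed-form least-squares line fit via the normal equations.
oracle_detrend <- function(x) {
  n <- length(x)
  X <- cbind(1, seq_len(n))
  beta <- solve(t(X) %*% X, t(X) %*% x)
  as.numeric(x - X %*% beta)
}

# Naive centered moving average with reflect padding (edge not repeated).
oracle_moving_average <- function(x, w) {
  n <- length(x)
  h <- (w - 1) %/% 2
  xp <- c(rev(x[2:(h + 1)]), x, rev(x[(n - h):(n - 1)]))
  vapply(seq_len(n), function(i) mean(xp[i:(i + w - 1)]), 0)
}

# Spectral amplitude at one frequency (rectangular-window DFT bin).
oracle_amp_at <- function(x, fps, f) {
  n <- length(x)
  k <- round(f * n / fps)
  Mod(fft(x))[k + 1]
}

# Even-odd (ray crossing) point-in-polygon test, one point at a time.
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(vx, vy, height, width) {
  m <- matrix(FALSE, height, width)
  for (r in seq_len(height)) {
    for (cc in seq_len(width)) {
      m[r, cc] <- oracle_point_in_polygon(cc - 0.5, r - 0.5, vx, vy)
    }
  }
  m
}

# Brute-force Otsu: maximize between-class variance over all splits;
# tie rule = plateau midpoint (floor of mean of tied maximizers).
oracle_otsu <- function(hist) {
  p <- hist / sum(hist)
  v <- 0:255
  sb <- rep(-Inf, 255)
  for (L in 0:254) {
    w0 <- sum(p[1:(L + 1)])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:(L + 1)] * v[1:(L + 1)]) / w0
    mu1 <- sum(p[(L + 2):256] * v[(L + 2):256]) / w1
    sb[L + 1] <- w0 * w1 * (mu0 - mu1)^2
  }
  tied <- which(sb >= max(sb) - 1e-9 * max(1, max(sb)))
  as.integer(floor(mean(tied))) - 1L
}

# Entropy-sum objective recomputed from its definition.
oracle_plateau_objective <- function(hist, level, lower, upper) {
  ent <- function(h) {
    h <- pmin(h, upper)
    h[h > 0 & h < lower] <- lower
    s <- sum(h)
    if (s == 0) return(0)
    p <- h[h > 0] / s
    -sum(p * log2(p))
  }
  ent(hist[1:(level + 1)]) + ent(hist[(level + 2):256])
}

# Uniform random test frame.
random_frame <- function(h, w, seed = 1) {
  withr::with_seed(seed,
    array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3)))
}

# A frame with a solid rectangular patch over a uniform background.
patch_frame <- function(h, w, box, patch_rgb, bg = c(40, 40, 40)) {
  fr <- array(0L, dim = c(h, w, 3))
  for (ci in 1:3) fr[, , ci] <- bg[ci]
  rows <- (box$y + 1):(box$y + box$h)
  cols <- (box$x + 1):(box$x + box$w)
  for (ci in 1:3) fr[rows, cols, ci] <- patch_rgb[ci]
  fr
}
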