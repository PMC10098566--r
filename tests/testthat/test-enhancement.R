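test_that("Otsu segmentation matches the brute-force oracle", {
  # bimodal: mass only at bins 50 and 200
  h <- numeric(256)
  h[51] <- 120; h[201] <- 80
  lev <- segment_histogram(h)
  expect_gt(lev, 50)
  expect_lt(lev, 200)
  expect_equal(lev, oracle_otsu(h))
  # uniform: symmetric, tie broken to the lowest maximizer
  hu <- rep(4, 256)
  expect_equal(segment_histogram(hu), 127)
  expect_equal(segment_histogram(hu), oracle_otsu(hu))
  # random histograms
  withr::with_seed(3, {
    for (i in 1:5) {
      hr <- rpois(256, 3)
      hr[1] <- hr[1] + 1  # ensure nonzero
      expect_equal(segment_histogram(hr), oracle_otsu(hr))
    }
  })
})

test_that("single-bin histograms return that bin", {
  h <- numeric(256)
  h[11] <- 42  # bin value 10
  expect_equal(segment_histogram(h), 10)
  expect_error(segment_histogram(numeric(256)), "nonzero")
})

test_that("the plateau objective equals its direct recomputation", {
  withr::with_seed(8, {
    h <- rpois(256, 10)
    lev <- segment_histogram(h)
    for (cand in list(c(5, 40), c(1, 8), c(0, 100))) {
      expect_equal(plateau_objective(h, lev, cand[1], cand[2]),
                   oracle_plateau_objective(h, lev, cand[1], cand[2]))
    }
    expect_identical(plateau_objective(h, lev, 10, 10), -Inf)
  })
})

test_that("the optimizer is seeded-deterministic and elitist", {
  withr::with_seed(9, h <- rpois(256, 6))
  lev <- segment_histogram(h)
  p1 <- optimize_plateaus(h, lev, cs_config(seed = 5))
  p2 <- optimize_plateaus(h, lev, cs_config(seed = 5))
  expect_identical(p1, p2)
  # more iterations can only improve on the best initial nest
  p0 <- optimize_plateaus(h, lev, cs_config(iterations = 0, seed = 5))
  expect_gte(p1$objective, p0$objective)
  expect_lt(p1$lower_plateau, p1$upper_plateau)
})

test_that("on a tiny candidate grid the optimizer matches the grid argmax", {
  withr::with_seed(10, h <- rpois(256, 6))
  lev <- segment_histogram(h)
  grid <- rbind(c(1, 3), c(2, 12), c(5, 40))
  fit <- apply(grid, 1, function(cand) {
    oracle_plateau_objective(h, lev, cand[1], cand[2])
  })
  got <- optimize_plateaus(h, lev, cs_config(seed = 2), candidates = grid)
  expect_equal(c(got$lower_plateau, got$upper_plateau),
               grid[which.max(fit), ])
  expect_equal(got$objective, max(fit))
})

test_that("the equalization mapping is monotone with outputs in range", {
  px <- withr::with_seed(12,
    matrix(sample(30:220, 300, replace = TRUE), ncol = 3))
  res <- apply_double_plateau_equalization(px, plateau_params(2, 20, 128))
  expect_length(res$mapping, 256)
  expect_true(all(diff(res$mapping) >= 0))
  expect_true(all(res$mapping >= 0 & res$mapping <= 255))
  expect_true(all(res$pixels >= 0 & res$pixels <= 255))
})

test_that("a constant ROI stays constant", {
  px <- matrix(rep(c(50L, 60L, 70L), each = 20), ncol = 3)
  res <- apply_double_plateau_equalization(px, plateau_params(0, 1000, 128))
  expect_equal(nrow(unique(res$pixels)), 1)
})

test_that("disabled plateaus reduce to per-segment histogram equalization", {
  px <- withr::with_seed(13,
    matrix(sample(0:255, 600, replace = TRUE), ncol = 3))
  y <- pmin(pmax(round(0.299 * px[, 1] + 0.587 * px[, 2] + 0.114 * px[, 3]),
                 0), 255)
  hist <- tabulate(y + 1, nbins = 256)
  L <- 127L
  # lower = 0 disables raising; upper >= max(hist) disables clipping
  res <- apply_double_plateau_equalization(
    px, plateau_params(0, max(hist) + 1, L))
  # classical per-segment HE oracle
  he <- function(h, lo, hi) as.integer(lo + round((hi - lo) * cumsum(h) / sum(h)))
  expected <- c(he(hist[1:(L + 1)], 0, L), he(hist[(L + 2):256], L + 1, 255))
  expect_identical(res$mapping, expected)
})

test_that("chromatic differences survive enhancement where unclipped", {
  px <- withr::with_seed(14,
    matrix(sample(60:180, 300, replace = TRUE), ncol = 3))
  res <- apply_double_plateau_equalization(px, plateau_params(1, 30, 120))
  unclipped <- apply(res$pixels, 1, function(v) all(v > 0 & v < 255))
  expect_gt(sum(unclipped), 0)
  expect_equal(res$pixels[unclipped, 1] - res$pixels[unclipped, 2],
               px[unclipped, 1] - px[unclipped, 2])
  expect_equal(res$pixels[unclipped, 2] - res$pixels[unclipped, 3],
               px[unclipped, 2] - px[unclipped, 3])
})

test_that("the disabled stage is the identity mapping", {
  expect_identical(identity_mapping(), 0:255)
  expect_error(plateau_params(10, 5, 128), "lower")
})
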