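test_that("degenerate config yields constant channels at baseline", {
  cfg <- synth_config(pulse_amplitude = 0, noise_sd = 0,
                      illum_drift_amp = 0, baseline_rgb = c(120, 100, 90),
                      fps = 30, duration_s = 5)
  tr <- generate_trace(cfg)
  expect_true(all(tr$r == 120))
  expect_true(all(tr$g == 100))
  expect_true(all(tr$b == 90))
})

test_that("sample count is round(fps * duration_s)", {
  tr <- generate_trace(synth_config(fps = 30, duration_s = 30))
  expect_length(tr$r, 900)
  expect_length(tr$g, 900)
  expect_length(tr$b, 900)
  # non-integer product rounds
  tr2 <- generate_trace(synth_config(fps = 29.97, duration_s = 10))
  expect_length(tr2$g, round(29.97 * 10))
})

test_that("clean trace's dominant non-DC peak sits at hr_bpm/60 Hz", {
  for (hr in c(48, 72, 150)) {
    cfg <- synth_config(hr_bpm = hr, fps = 30, duration_s = 60,
                        noise_sd = 0)
    tr <- generate_trace(cfg)
    f <- oracle_peak_freq(tr$g - mean(tr$g), 30)
    expect_lt(abs(f - hr / 60), 1 / 60 + 1e-12)  # within one FFT bin
  }
})

test_that("generation is reproducible from the seed", {
  cfg <- synth_config(noise_sd = 1.5, duration_s = 5, seed = 42)
  t1 <- generate_trace(cfg)
  t2 <- generate_trace(cfg)
  expect_identical(t1, t2)
  t3 <- generate_trace(synth_config(noise_sd = 1.5, duration_s = 5,
                                    seed = 43))
  expect_false(identical(t1$g, t3$g))
})

test_that("generate_trace does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_trace(synth_config(noise_sd = 1, duration_s = 2)))
  expect_identical(runif(1), before)
})

test_that("modulation beyond the 8-bit range clips with a warning", {
  cfg <- synth_config(baseline_rgb = c(254, 254, 254), pulse_amplitude = 10,
                      channel_weights = c(1, 1, 1), duration_s = 5)
  expect_warning(tr <- generate_trace(cfg), "clipped")
  expect_true(all(tr$g <= 255 & tr$g >= 0))
})

test_that("invalid configs are rejected", {
  expect_error(synth_config(hr_bpm = 0), "hr_bpm")
  expect_error(synth_config(fps = -1), "fps")
  expect_error(synth_config(baseline_rgb = c(300, 0, 0)), "baseline_rgb")
  expect_error(generate_trace(list()), "synth_config")
})

test_that("rendered frames honor the shape contract", {
  cfg <- synth_config(fps = 10, duration_s = 1)
  vid <- generate_video(cfg, width = 20, height = 12, roi_fraction = 0.5)
  expect_length(vid$frames, 10)
  for (fr in vid$frames) {
    expect_identical(dim(fr), c(12L, 20L, 3L))
    expect_true(all(fr >= 0 & fr <= 255))
  }
  expect_identical(dim(vid$mask), c(12L, 20L))
  expect_error(generate_video(cfg, width = 0, height = 10), "positive")
  expect_error(generate_video(cfg, 10, 10, roi_fraction = 1.5), "roi_fraction")
})

test_that("ROI mean of rendered frames reproduces the trace within 0.5", {
  cfg <- synth_config(hr_bpm = 72, fps = 30, duration_s = 5,
                      pulse_amplitude = 3, noise_sd = 0)
  vid <- generate_video(cfg, width = 32, height = 24, roi_fraction = 0.5)
  for (i in seq_along(vid$frames)) {
    s <- extract_mean_rgb(vid$frames[[i]], vid$mask)
    expect_true(s$valid)
    expect_lt(abs(s$rgb[1] - vid$trace$r[i]), 0.5 + 1e-12)
    expect_lt(abs(s$rgb[2] - vid$trace$g[i]), 0.5 + 1e-12)
    expect_lt(abs(s$rgb[3] - vid$trace$b[i]), 0.5 + 1e-12)
  }
})

test_that("same seed renders byte-identical video files with sidecars", {
  cfg <- synth_config(noise_sd = 1, duration_s = 2, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_synthetic_video(cfg, d1, width = 16, height = 12)
  p2 <- write_synthetic_video(cfg, d2, width = 16, height = 12)
  expect_identical(readBin(p1$video, "raw", file.size(p1$video)),
                   readBin(p2$video, "raw", file.size(p2$video)))
  expect_identical(readLines(p1$gt), readLines(p2$gt))
  expect_true(file.exists(p1$roi))
  gt <- read.csv(p1$gt)
  expect_identical(names(gt), c("time_s", "hr_bpm"))
  expect_identical(gt$time_s, 0:1)  # 1 Hz sidecar
})

test_that("heart rates outside the readable band warn but generate", {
  cfg <- synth_config(hr_bpm = 250, duration_s = 1)
  d <- withr::local_tempdir()
  expect_warning(write_synthetic_video(cfg, d, width = 8, height = 8),
                 "42-240")
  expect_true(file.exists(file.path(d, "video.ppm")))
})
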