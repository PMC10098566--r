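test_that("the landmark schema has 81 indices: 68 base + 13 forehead", {
  expect_length(landmark_schema$base, 68)
  expect_length(landmark_schema$forehead, 13)
  all_idx <- c(landmark_schema$base, landmark_schema$forehead)
  expect_length(all_idx, 81)
  expect_identical(sort(all_idx), 1:81)  # each index used exactly once
  expect_true(all(landmark_schema$brows %in% landmark_schema$base))
})

test_that("extract_landmarks always yields 81 in-frame points", {
  frame <- patch_frame(60, 80, list(x = 20, y = 10, w = 40, h = 32),
                       c(150, 110, 95))
  be <- roi_backend_fixture(list(x = 20, y = 10, w = 40, h = 32))
  box <- detect_face(frame, be)
  pts <- extract_landmarks(frame, box, be)
  expect_identical(dim(pts), c(81L, 2L))
  expect_true(all(pts[, 1] >= 0 & pts[, 1] <= 80))
  expect_true(all(pts[, 2] >= 0 & pts[, 2] <= 60))
  # analytic grid positions of the fixture layout
  expect_equal(pts[landmark_schema$forehead, 2], rep(10, 13))
  expect_equal(pts[landmark_schema$brows, 2], rep(10 + 0.25 * 32, 10))
  expect_equal(range(pts[landmark_schema$forehead, 1]),
               c(20 + 0.1 * 40, 20 + 0.9 * 40))
})

test_that("patch detection returns the rendered patch's exact box", {
  box <- list(x = 12, y = 5, w = 20, h = 15)
  frame <- patch_frame(40, 50, box, c(200, 150, 120))
  got <- detect_face(frame, roi_backend_patch())
  expect_equal(got, box)
  # no face-like structure -> absent
  flat <- patch_frame(40, 50, list(x = 1, y = 1, w = 1, h = 1), c(40, 40, 40))
  expect_null(detect_face(flat, roi_backend_patch()))
})

test_that("the largest of several candidate boxes is selected", {
  frame <- patch_frame(60, 60, list(x = 2, y = 2, w = 10, h = 10),
                       c(200, 150, 120))
  frame[31:50, 31:50, 1] <- 220  # 400 px^2 patch vs 100 px^2
  got <- detect_face(frame, roi_backend_patch())
  expect_equal(got, list(x = 30L, y = 30L, w = 20L, h = 20L))
})

test_that("a missing landmark model is a configuration error naming it", {
  expect_error(roi_backend_dlib("/no/model_81.dat"), "model_81.dat")
})

test_that("fixture landmarks forming a 40 x 20 rectangle give area 800", {
  # forehead span: x in [x0 + 0.1 w, x0 + 0.9 w], y in [y0, y0 + 0.25 h]
  # box (5, 10, 50, 80) -> rectangle [10, 50] x [10, 30]: 40 x 20 px
  box <- list(x = 5, y = 10, w = 50, h = 80)
  pts <- geometric_landmarks(box)
  mask <- forehead_mask(pts, c(100, 100))
  expect_equal(mask$area, 800)
  expect_true(all(which(colSums(mask$mask) > 0) %in% 11:50))
  expect_true(all(which(rowSums(mask$mask) > 0) %in% 11:30))
})

test_that("rasterization agrees with the even-odd oracle on integer polygons", {
  polys <- list(
    list(vx = c(2, 12, 12, 2), vy = c(3, 3, 9, 9)),            # rectangle
    list(vx = c(1, 13, 7), vy = c(12, 12, 1)),                 # triangle
    list(vx = c(2, 12, 12, 7, 2), vy = c(2, 2, 12, 7, 12)),    # concave
    list(vx = c(1, 13, 1, 13), vy = c(1, 11, 11, 1))           # self-crossing
  )
  for (p in polys) {
    got <- rppg:::rasterize_polygon(p$vx, p$vy, 14, 15)
    expect_identical(got, oracle_rasterize(p$vx, p$vy, 14, 15))
  }
})

test_that("random simple polygons match the even-odd oracle", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      k <- sample(3:7, 1)
      th <- sort(runif(k, 0, 2 * pi))
      rad <- runif(k, 2, 6)
      vx <- round(7 + rad * cos(th))
      vy <- round(7 + rad * sin(th))
      got <- rppg:::rasterize_polygon(vx, vy, 15, 15)
      expect_identical(got, oracle_rasterize(vx, vy, 15, 15))
    }
  })
})

test_that("masks are clipped to the frame", {
  box <- list(x = -20, y = -10, w = 60, h = 60)
  pts <- geometric_landmarks(box)
  mask <- forehead_mask(pts, c(30, 30))
  expect_lte(mask$area, 30 * 30)
  expect_identical(dim(mask$mask), c(30L, 30L))
})

test_that("degenerate landmark sets yield the empty-mask signal", {
  box <- list(x = 5, y = 10, w = 50, h = 80)
  pts <- geometric_landmarks(box)
  flipped <- pts
  flipped[, 2] <- 100 - pts[, 2]  # forehead now below the brow line
  expect_equal(forehead_mask(flipped, c(100, 100))$area, 0)
  collinear <- pts
  collinear[landmark_schema$forehead, 2] <- pts[landmark_schema$brows[1], 2]
  collinear[landmark_schema$brows, 2] <- pts[landmark_schema$brows[1], 2]
  expect_equal(forehead_mask(collinear, c(100, 100))$area, 0)
  expect_error(forehead_mask(pts[1:10, ], c(100, 100)), "81")
})

test_that("per-frame masks are identical on a static synthetic video", {
  cfg <- synth_config(duration_s = 1, fps = 10, noise_sd = 2)
  vid <- generate_video(cfg, width = 40, height = 30, roi_fraction = 0.6)
  be <- roi_backend_fixture(vid$box)
  masks <- lapply(vid$frames, function(fr) {
    forehead_mask(extract_landmarks(fr, detect_face(fr, be), be),
                  dim(fr)[1:2])$mask
  })
  for (m in masks[-1]) expect_identical(m, masks[[1]])
  expect_gt(sum(masks[[1]]), 0)
})
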