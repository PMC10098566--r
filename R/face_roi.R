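# Face detection, the 81-point landmark schema (68 base points + 13
# forehead-extension points) and rasterization of the forehead ROI mask.
#
# The landmark schema follows the common 68-point convention (1-based
# here): jaw 1-17, eyebrows 18-27, nose 28-36, eyes 37-48, mouth 49-68;
# indices 69-81 are the 13 additional points delineating the forehead.
# The forehead ROI polygon is bounded below by the eyebrow-top line and
# above/laterally by the 13 forehead points.
#
# Backends are pluggable so the heavy landmark models are optional: a
# deterministic geometric fixture backend (analytic positions from a
# declared box), a luminance-patch detector for synthetic frames, and a
# dlib-model backend stub whose constructor validates the model path.

#' Landmark schema index sets
#'
#' 1-based index vectors into the 81-point landmark matrix.
#' @format A list with `base` (1:68), `forehead` (69:81, the 13 forehead
#'   extension points) and `brows` (18:27, the eyebrow points whose top
#'   line bounds the forehead ROI from below).
#' @export
landmark_schema <- list(
  base = 1:68,
  forehead = 69:81,
  brows = 18:27
)

#' Fixture detection backend with a declared face box
#'
#' Returns the declared box for every frame; landmark positions come from
#' the deterministic geometric layout of [geometric_landmarks()]. Used to
#' test the measurement chain without landmark models, and to drive the
#' pipeline from a synthetic video's `roi.json` sidecar.
#'
#' @param box A list with 0-based integer fields `x`, `y`, `w`, `h`.
#' @return A backend object.
#' @export
roi_backend_fixture <- function(box) {
  stopifnot(all(c("x", "y", "w", "h") %in% names(box)))
  if (box$w <= 0 || box$h <= 0) stop("box must have positive size", call. = FALSE)
  structure(list(name = "fixture", box = box), class = "roi_backend")
}

#' Luminance-patch detection backend
#'
#' Detects the face (or, on synthetic fixtures, the rendered patch) as the
#' largest connected component of pixels whose color differs from the
#' frame-border background color by more than `tol`. Returns its exact
#' bounding box.
#'
#' @param tol Per-channel intensity difference threshold.
#' @return A backend object.
#' @export
roi_backend_patch <- function(tol = 10) {
  structure(list(name = "patch", tol = tol), class = "roi_backend")
}

#' Dlib landmark-model backend (interface stub)
#'
#' The standard deployment uses a HoG + SVM face detector and a 68-point
#' landmark model extended with 13 forehead points. No dlib runtime is
#' available in this build: the constructor validates the model path (a
#' missing file is a configuration error naming the file) and any use
#' errors with a clear message. The geometric backend covers testing.
#'
#' @param model_path Path to the 81-point shape-predictor model file.
#' @return A backend object.
#' @export
roi_backend_dlib <- function(model_path) {
  if (!file.exists(model_path)) {
    stop(sprintf("landmark model file not found: '%s'", model_path),
         call. = FALSE)
  }
  structure(list(name = "dlib", model_path = model_path),
            class = "roi_backend")
}

# Connected components (4-neighborhood) of a logical matrix; returns an
# integer label matrix. BFS with an integer stack; frames are small.
label_components <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(m)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < h) p + 1L,
                  if (cc > 1L) p - h, if (cc < w) p + h)) {
        if (m[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

#' Detect the face in a frame
#'
#' At most one box is returned; when several candidates exist the largest
#' (by area) wins, matching a single-subject protocol. Absence of a face
#' is a value (`NULL`), not an error.
#'
#' @param frame `height x width x 3` integer array.
#' @param backend A `roi_backend` object.
#' @return A list `x`, `y`, `w`, `h` (0-based, pixels) or `NULL`.
#' @export
detect_face <- function(frame, backend) {
  stopifnot(inherits(backend, "roi_backend"))
  switch(backend$name,
    fixture = backend$box,
    patch = {
      h <- dim(frame)[1]; w <- dim(frame)[2]
      border <- rbind(frame[1, , ], frame[h, , ], frame[, 1, ], frame[, w, ])
      key <- paste(border[, 1], border[, 2], border[, 3])
      bg <- border[match(names(which.max(table(key))), key), ]
      diffm <- abs(frame[, , 1] - bg[1]) > backend$tol |
               abs(frame[, , 2] - bg[2]) > backend$tol |
               abs(frame[, , 3] - bg[3]) > backend$tol
      if (!any(diffm)) return(NULL)
      lab <- label_components(diffm)
      sizes <- tabulate(lab)
      best <- which.max(sizes)
      idx <- which(lab == best, arr.ind = TRUE)
      r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
      c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
      list(x = c0 - 1L, y = r0 - 1L, w = c1 - c0 + 1L, h = r1 - r0 + 1L)
    },
    dlib = stop("dlib backend: runtime not available in this build",
                call. = FALSE),
    stop("unknown backend", call. = FALSE)
  )
}

#' Deterministic geometric landmark layout for a face box
#'
#' Places the 81 schema points at analytic positions inside a box
#' (continuous 0-based pixel coordinates): the 10 eyebrow points evenly
#' spaced on the line `y = y0 + 0.25 h` over `x in [x0 + 0.1 w,
#' x0 + 0.9 w]`, the 13 forehead points evenly spaced on `y = y0` over the
#' same x-range (so the forehead ROI polygon is an axis-aligned
#' rectangle), the jaw on a lower half-ellipse, and eyes/nose/mouth at
#' fixed fractional positions. Every index is used exactly once.
#'
#' @param box List `x`, `y`, `w`, `h` (0-based).
#' @return An 81 x 2 numeric matrix of (x, y) positions.
#' @export
geometric_landmarks <- function(box) {
  x0 <- box$x; y0 <- box$y; w <- box$w; h <- box$h
  pts <- matrix(NA_real_, 81, 2)
  # jaw 1-17: lower half-ellipse
  th <- seq(pi, 2 * pi, length.out = 17)
  pts[1:17, 1] <- x0 + w / 2 + (w / 2) * cos(th)
  pts[1:17, 2] <- y0 + 0.6 * h - (0.4 * h) * cos(th - pi)  # chin dips down
  # eyebrows 18-27: the forehead's lower boundary line
  bx <- seq(x0 + 0.1 * w, x0 + 0.9 * w, length.out = 10)
  pts[18:27, 1] <- bx
  pts[18:27, 2] <- y0 + 0.25 * h
  # nose 28-36
  pts[28:36, 1] <- x0 + w / 2 + c(0, 0, 0, 0, -0.1, -0.05, 0, 0.05, 0.1) * w
  pts[28:36, 2] <- y0 + c(0.35, 0.42, 0.49, 0.56, 0.60, 0.62, 0.63, 0.62, 0.60) * h
  # eyes 37-48 (two hexagons)
  ex <- c(0.20, 0.26, 0.32, 0.38, 0.32, 0.26)
  ey <- c(0.40, 0.37, 0.37, 0.40, 0.43, 0.43)
  pts[37:42, 1] <- x0 + ex * w
  pts[37:42, 2] <- y0 + ey * h
  pts[43:48, 1] <- x0 + (1 - rev(ex)) * w
  pts[43:48, 2] <- y0 + rev(ey) * h
  # mouth 49-68: outer 12 + inner 8 ring
  mth <- seq(0, 2 * pi, length.out = 13)[-13]
  pts[49:60, 1] <- x0 + w / 2 + 0.18 * w * cos(mth)
  pts[49:60, 2] <- y0 + 0.78 * h + 0.08 * h * sin(mth)
  mth2 <- seq(0, 2 * pi, length.out = 9)[-9]
  pts[61:68, 1] <- x0 + w / 2 + 0.10 * w * cos(mth2)
  pts[61:68, 2] <- y0 + 0.78 * h + 0.04 * h * sin(mth2)
  # forehead extension 69-81: the ROI's upper boundary
  fx <- seq(x0 + 0.1 * w, x0 + 0.9 * w, length.out = 13)
  pts[69:81, 1] <- fx
  pts[69:81, 2] <- y0
  pts
}

#' Extract the 81-point landmark set for a detected face
#'
#' @param frame `height x width x 3` integer array.
#' @param box Face box from [detect_face()].
#' @param backend A `roi_backend`; the fixture and patch backends use the
#'   geometric layout, the dlib backend requires its (unavailable)
#'   runtime.
#' @return An 81 x 2 matrix of (x, y) positions, clipped to the frame.
#' @export
extract_landmarks <- function(frame, box, backend) {
  stopifnot(inherits(backend, "roi_backend"))
  if (backend$name == "dlib") {
    stop("dlib backend: runtime not available in this build", call. = FALSE)
  }
  pts <- geometric_landmarks(box)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  pts[, 1] <- pmin(pmax(pts[, 1], 0), w)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), h)
  pts
}

# Even-odd polygon rasterization. Vertices are continuous 0-based pixel
# coordinates; pixel (row i, col j) (1-based) occupies
# [j-1, j) x [i-1, i) and is covered iff its center (j-0.5, i-0.5)
# falls inside the polygon under the even-odd (ray crossing) rule.
rasterize_polygon <- function(vx, vy, height, width) {
  mask <- matrix(FALSE, height, width)
  n <- length(vx)
  if (n < 3) return(mask)
  c0 <- max(1L, floor(min(vx) + 0.5) + 1L)
  c1 <- min(width, ceiling(max(vx) + 0.5))
  r0 <- max(1L, floor(min(vy) + 0.5) + 1L)
  r1 <- min(height, ceiling(max(vy) + 0.5))
  if (c0 > c1 || r0 > r1) return(mask)
  px <- (c0:c1) - 0.5
  py <- (r0:r1) - 0.5
  sub <- matrix(FALSE, length(py), length(px))
  j <- n
  for (i in seq_len(n)) {
    y1 <- vy[i]; y2 <- vy[j]; x1 <- vx[i]; x2 <- vx[j]
    if (y1 != y2) {
      # rows whose center lies strictly between the edge's y-extent
      hit <- (py >= pmin(y1, y2)) & (py < pmax(y1, y2))
      if (any(hit)) {
        xint <- x1 + (py[hit] - y1) / (y2 - y1) * (x2 - x1)
        cross <- outer(xint, px, FUN = ">")  # center left of intersection
        sub[hit, ] <- xor(sub[hit, , drop = FALSE], cross)
      }
    }
    j <- i
  }
  mask[r0:r1, c0:c1] <- sub
  mask
}

#' Rasterize the forehead ROI mask from a landmark set
#'
#' The ROI polygon runs along the 13 forehead-extension points (left to
#' right) and closes along the eyebrow points (right to left); it is
#' filled with the even-odd rule at pixel centers and clipped to the
#' frame. A degenerate polygon — zero area, or a flipped set in which the
#' forehead points do not lie above the eyebrow line — yields an empty
#' mask (`area = 0`), which downstream stages treat as "no valid ROI".
#'
#' @param landmarks 81 x 2 landmark matrix.
#' @param frame_shape `c(height, width)`.
#' @return A `roi_mask` object: list with logical `mask` and integer
#'   `area` (pixels).
#' @export
forehead_mask <- function(landmarks, frame_shape) {
  if (!is.matrix(landmarks) || nrow(landmarks) != 81L) {
    stop("landmarks must be an 81 x 2 matrix", call. = FALSE)
  }
  h <- frame_shape[1]; w <- frame_shape[2]
  fh <- landmarks[landmark_schema$forehead, , drop = FALSE]
  br <- landmarks[landmark_schema$brows, , drop = FALSE]
  empty <- function() {
    structure(list(mask = matrix(FALSE, h, w), area = 0L),
              class = "roi_mask")
  }
  # orientation sanity: forehead points must sit above (smaller y than)
  # the eyebrow line in image coordinates
  if (mean(fh[, 2]) >= mean(br[, 2])) return(empty())
  fh <- fh[order(fh[, 1]), , drop = FALSE]
  br <- br[order(br[, 1], decreasing = TRUE), , drop = FALSE]
  vx <- c(fh[, 1], br[, 1])
  vy <- c(fh[, 2], br[, 2])
  # shoelace area; collinear/degenerate polygons are rejected
  n <- length(vx)
  area2 <- abs(sum(vx * vy[c(2:n, 1)] - vx[c(2:n, 1)] * vy))
  if (area2 < 1e-9) return(empty())
  mask <- rasterize_polygon(vx, vy, h, w)
  structure(list(mask = mask, area = sum(mask)), class = "roi_mask")
}
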