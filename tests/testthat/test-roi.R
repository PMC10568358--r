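const_frame <- function(h, w, rgb) {
  f <- array(0, c(h, w, 3))
  for (c3 in 1:3) f[, , c3] <- rgb[c3]
  f
}

test_that("extract_trace averages pixels exactly", {
  rois <- roi_set(forehead = c(2, 6, 1, 4), left_cheek = c(0, 3, 5, 9),
                  right_cheek = c(6, 10, 5, 9))

  # constant-colour frames: every region reports the colour itself
  vid <- video_sequence(list(const_frame(10, 10, c(10, 20, 30)),
                             const_frame(10, 10, c(10, 20, 30))), fps = 2)
  traces <- extract_trace(vid, rois)
  for (nm in names(traces)) {
    expect_equal(traces[[nm]]$R, c(10, 10))
    expect_equal(traces[[nm]]$G, c(20, 20))
    expect_equal(traces[[nm]]$B, c(30, 30))
  }

  # two-pixel region: mean of (0,0,0) and (2,4,6) is (1,2,3)
  f <- const_frame(4, 4, c(0, 0, 0))
  f[1, 2, ] <- c(2, 4, 6)
  vid2 <- video_sequence(list(f, f), fps = 2)
  two_px <- roi_set(forehead = c(0, 2, 0, 1), left_cheek = c(0, 2, 0, 1),
                    right_cheek = c(0, 2, 0, 1))
  tr <- extract_trace(vid2, two_px)$forehead
  expect_equal(c(tr$R[1], tr$G[1], tr$B[1]), c(1, 2, 3))

  # checkerboard of 0/255 in R over an even-sized region averages to 127.5
  f <- const_frame(8, 8, c(0, 100, 100))
  f[, , 1] <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 255, 0))
  vid3 <- video_sequence(list(f, f), fps = 2)
  board <- roi_set(forehead = c(0, 8, 0, 8), left_cheek = c(0, 8, 0, 8),
                   right_cheek = c(0, 8, 0, 8))
  expect_equal(extract_trace(vid3, board)$forehead$R[1], 127.5)
  expect_equal(extract_trace(vid3, board)$forehead$R[1],
               oracle_roi_mean(f, c(0, 8, 0, 8))[1])
})

test_that("extract_trace matches the per-pixel brute-force oracle", {
  set.seed(401)
  for (rep in 1:5) {
    h <- sample(6:12, 1); w <- sample(6:12, 1)
    f <- array(runif(h * w * 3, 0, 255), c(h, w, 3))
    x0 <- sample(0:(w - 3), 1); x1 <- sample((x0 + 2):w, 1)
    y0 <- sample(0:(h - 3), 1); y1 <- sample((y0 + 2):h, 1)
    box <- c(x0, x1, y0, y1)
    rois <- roi_set(forehead = box, left_cheek = box, right_cheek = box)
    tr <- extract_trace(video_sequence(list(f, f), fps = 2), rois)$forehead
    expect_equal(c(tr$R[1], tr$G[1], tr$B[1]), oracle_roi_mean(f, box),
                 tolerance = 1e-12)
    # trace values bounded by region channel extremes
    for (c3 in 1:3) {
      px <- f[(y0 + 1):y1, (x0 + 1):x1, c3]
      val <- c(tr$R[1], tr$G[1], tr$B[1])[c3]
      expect_gte(val, min(px)); expect_lte(val, max(px))
    }
  }
})

test_that("regions outside the frame raise a bounds error", {
  vid <- video_sequence(list(const_frame(8, 8, c(1, 2, 3)),
                             const_frame(8, 8, c(1, 2, 3))), fps = 2)
  bad <- roi_set(forehead = c(4, 12, 0, 4), left_cheek = c(0, 4, 0, 4),
                 right_cheek = c(0, 4, 0, 4))
  expect_error(extract_trace(vid, bad), "outside frame bounds")
})

test_that("fuse_traces is an unweighted, order-invariant channel mean", {
  t1 <- rgb_trace(c(0, 1), c(0, 1), c(0, 1), fps = 30)
  t2 <- rgb_trace(c(0, 1), c(0, 1), c(0, 1), fps = 30)
  t3 <- rgb_trace(c(3, 1), c(3, 1), c(3, 1), fps = 30)

  # identical traces fuse to themselves
  same <- fuse_traces(list(t1, t2, t1))
  expect_equal(same$R, t1$R)

  # region values 0, 0, 3 average to 1
  fused <- fuse_traces(list(t1, t2, t3))
  expect_equal(fused$R[1], 1)
  expect_equal(fused$roi_name, "fused")

  # permutation invariance
  perm <- fuse_traces(list(t3, t1, t2))
  expect_equal(perm$R, fused$R)
  expect_equal(perm$G, fused$G)

  short <- rgb_trace(c(0, 1, 2), c(0, 1, 2), c(0, 1, 2), fps = 30)
  expect_error(fuse_traces(list(t1, short, t3)), "length")
})

test_that("detect_rois falls back, holds last valid regions, and errors", {
  frames <- replicate(10, const_frame(40, 60, c(50, 50, 50)), simplify = FALSE)
  vid <- video_sequence(frames, fps = 10)
  fixed <- roi_set(forehead = c(20, 40, 2, 8), left_cheek = c(5, 18, 15, 30),
                   right_cheek = c(42, 55, 15, 30))

  # face-free video with a fixed-coordinates fallback
  expect_identical(detect_rois(vid, detector = NULL, fallback = fixed), fixed)
  expect_error(detect_rois(vid, detector = NULL), "no face")

  # detector failing on one frame: that frame reuses the previous regions
  lm <- list(brow_left = c(15, 12), brow_right = c(45, 12),
             eye_left = c(12, 16), eye_right = c(48, 16),
             nose_left = c(25, 24), nose_right = c(35, 24),
             jaw_left = c(14, 34), jaw_right = c(46, 34),
             hairline = c(30, 2))
  shifty <- local({
    cnt <- 0L
    function(frame) {
      cnt <<- cnt + 1L
      if (cnt == 4L) return(NULL)                          # fail frame 4 only
      lapply(lm, function(p) p + c(cnt - 1L, 0))           # drift each frame
    }
  })
  rois <- detect_rois(vid, detector = shifty)
  expect_identical(region_box_for_test(rois, "forehead", 4L),
                   region_box_for_test(rois, "forehead", 3L))
  expect_false(identical(region_box_for_test(rois, "forehead", 5L),
                         region_box_for_test(rois, "forehead", 4L)))

  # detection lost longer than the hold window errors out
  first_only <- local({
    n <- 0L
    function(frame) {
      n <<- n + 1L
      if (n == 1L) lm else NULL
    }
  })
  expect_error(detect_rois(vid, detector = first_only, max_hold_s = 0.5),
               "lost")
})

test_that("landmark-derived regions stay inside the frame and above brows", {
  lm <- list(brow_left = c(15, 12), brow_right = c(45, 12),
             eye_left = c(12, 16), eye_right = c(48, 16),
             nose_left = c(25, 24), nose_right = c(35, 24),
             jaw_left = c(14, 34), jaw_right = c(46, 34),
             hairline = c(30, 2))
  frames <- replicate(3, const_frame(40, 60, c(50, 50, 50)), simplify = FALSE)
  vid <- video_sequence(frames, fps = 10)
  rois <- detect_rois(vid, detector = function(frame) lm)
  fh <- region_box_for_test(rois, "forehead", 1L)
  expect_lte(fh[4], 12)                 # forehead ends at the brow line
  for (nm in c("forehead", "left_cheek", "right_cheek")) {
    b <- region_box_for_test(rois, nm, 1L)
    expect_gte(b[1], 0); expect_lte(b[2], 60)
    expect_gte(b[3], 0); expect_lte(b[4], 40)
    expect_gt(b[2], b[1]); expect_gt(b[4], b[3])
  }
  # end-to-end: landmark ROIs on a constant frame recover the colour
  tr <- extract_trace(vid, rois)
  expect_equal(fuse_traces(tr)$R, rep(50, 3))
})
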