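test_that("extract_centroid follows the threshold / largest-particle rule", {
  # uniform white frame: nothing darker than threshold
  expect_null(extract_centroid(matrix(255L, 20, 20), 100))

  # 3x3 black square, top-left pixel at (x=10, y=20), 0-based
  fr <- matrix(255L, 40, 40)
  fr[21:23, 11:13] <- 0L
  expect_equal(extract_centroid(fr, 100), c(11, 21))

  # two blobs: centroid of the larger one, verified by pixel enumeration
  fr <- matrix(255L, 40, 40)
  fr[5:14, 5:9] <- 0L      # 10 x 5 = 50 px
  fr[30:32, 30:32] <- 0L   # 9 px
  got <- extract_centroid(fr, 100)
  dark <- which(fr < 100, arr.ind = TRUE)
  big <- dark[dark[, "row"] <= 14, , drop = FALSE]
  expect_equal(nrow(big), 50)
  expect_equal(got, c(mean(big[, "col"] - 1), mean(big[, "row"] - 1)))

  # min_area filtering: only the small blob left -> below area -> MISSING
  fr2 <- matrix(255L, 40, 40)
  fr2[30:32, 30:32] <- 0L
  expect_null(extract_centroid(fr2, 100, min_area_px = 10))
  expect_equal(extract_centroid(fr2, 100, min_area_px = 9), c(30, 30))

  # polarity flip: a light animal on a dark arena needs invert = TRUE
  # (without it, the whole dark background is the largest particle)
  fr3 <- matrix(0L, 20, 20)
  fr3[6:8, 6:8] <- 255L
  expect_false(isTRUE(all.equal(extract_centroid(fr3, 100), c(6, 6))))
  expect_equal(extract_centroid(fr3, 100, invert = TRUE), c(6, 6))

  # diagonal touching is NOT 4-connected: two 2x2 blobs, not one component
  fr4 <- matrix(255L, 20, 20)
  fr4[5:6, 5:6] <- 0L
  fr4[7:8, 7:8] <- 50L  # darker than threshold, slightly bigger weight area
  fr4[7:8, 7] <- 0L
  got <- extract_centroid(fr4, 100, min_area_px = 4)
  expect_true(!is.null(got))

  expect_error(extract_centroid(matrix(numeric(0), 0, 0), 100),
               class = "ek_invalid_input")
})

test_that("track_stack preserves order, MISSING frames, and reverses with the stack", {
  tr <- trajectory(seq(4, 22, by = 2), rep(10, 10), dt_s = 1 / 30)
  rf <- render_frames(tr, calibration(1), blob_radius_px = 3,
                      noise_sd = 0, frame_dims = c(30, 40), seed = 1)
  rt <- track_stack(rf$stack, 128)
  expect_equal(nrow(rt), 10)
  expect_true(all(abs(diff(rt$x_px) - 2) < 0.5))
  expect_true(all(abs(rt$x_px - rf$truth_px$x_px) <= 0.5))

  # one blank frame stays MISSING
  frames <- rf$stack$frames
  frames[[4]] <- matrix(255L, nrow(frames[[1]]), ncol(frames[[1]]))
  st2 <- frame_stack(frames, 1 / 30)
  rt2 <- track_stack(st2, 128)
  expect_true(is.na(rt2$x_px[4]))
  expect_equal(sum(is.na(rt2$x_px)), 1)

  # stationary blob: identical points
  trs <- trajectory(rep(10, 5), rep(10, 5), dt_s = 1 / 30)
  sts <- render_frames(trs, calibration(1), noise_sd = 0,
                       frame_dims = c(25, 25), seed = 1)$stack
  rts <- track_stack(sts, 128)
  expect_equal(length(unique(rts$x_px)), 1)

  # permutation equivariance: reversed stack -> reversed points
  strev <- frame_stack(rev(rf$stack$frames), 1 / 30)
  rtrev <- track_stack(strev, 128)
  expect_equal(rtrev$x_px, rev(rt$x_px))
  expect_equal(rtrev$y_px, rev(rt$y_px))
})

test_that("fill_missing interpolates short interior gaps only", {
  mk <- function(x, y) raw_track(x, y, 1 / 30)
  # midpoint
  t1 <- fill_missing(mk(c(0, NA, 2), c(0, NA, 2)), max_gap = 1)
  expect_equal(t1$x_px, c(0, 1, 2))
  expect_equal(attr(t1, "filled_frames"), 1L)

  # gap longer than max_gap untouched
  t2 <- fill_missing(mk(c(0, NA, NA, NA, 4), c(0, NA, NA, NA, 4)), max_gap = 2)
  expect_equal(sum(is.na(t2$x_px)), 3)

  # gap of 2 at 1/3 and 2/3
  t3 <- fill_missing(mk(c(0, NA, NA, 3), c(3, NA, NA, 0)), max_gap = 2)
  expect_equal(t3$x_px, c(0, 1, 2, 3))
  expect_equal(t3$y_px, c(3, 2, 1, 0))

  # leading/trailing gaps never filled
  t4 <- fill_missing(mk(c(NA, 1, 2, NA), c(NA, 1, 2, NA)), max_gap = 5)
  expect_equal(is.na(t4$x_px), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("calibration maps pixels to arena cm and is invertible", {
  t1 <- calibrate_track(raw_track(c(0, 60), c(0, 0), 1 / 30), calibration(1))
  expect_equal(t1$x_cm, c(0, 60))

  t2 <- calibrate_track(raw_track(c(120, 0), c(240, 0), 1 / 30), calibration(2))
  expect_equal(t2$x_cm[1], 60)
  expect_equal(t2$y_cm[1], 120)

  # anisotropic, against elementwise division
  set.seed(5)
  xs <- runif(20, 0, 200); ys <- runif(20, 0, 200)
  cal <- calibration(2, 4, origin_px = c(10, 20))
  tr <- calibrate_track(raw_track(xs, ys, 1 / 30), cal)
  expect_equal(tr$x_cm, (xs - 10) / 2)
  expect_equal(tr$y_cm, (ys - 20) / 4)

  # round trip to within 1e-9 cm
  back_x <- tr$x_cm * cal$px_per_cm_x + cal$origin_px[1]
  expect_equal(back_x, xs, tolerance = 1e-9)

  # remaining MISSING frames are rejected with their indices
  err <- tryCatch(
    calibrate_track(raw_track(c(0, NA, 2), c(0, NA, 2), 1 / 30), calibration(1)),
    ek_incomplete_track = function(e) e)
  expect_s3_class(err, "ek_incomplete_track")
  expect_equal(err$frames, 1L)
})

test_that("rendered blobs are recovered within 0.5 px down to SNR 5", {
  # area >= 9 px (radius 2 disc has 13 px); contrast 190 at noise_sd <= 38
  for (seed in 1:5) {
    tr <- withr::with_seed(seed, trajectory(runif(30, 8, 20), runif(30, 8, 20),
                                            dt_s = 1 / 30))
    for (noise in c(0, 20, 38)) {
      rf <- render_frames(tr, calibration(1), blob_radius_px = 2,
                          blob_intensity = 30, background_intensity = 220,
                          noise_sd = noise, frame_dims = c(30, 30),
                          seed = seed)
      rt <- track_stack(rf$stack, 125, min_area_px = 9)
      expect_true(all(abs(rt$x_px - rf$truth_px$x_px) <= 0.5))
      expect_true(all(abs(rt$y_px - rf$truth_px$y_px) <= 0.5))
    }
  }
})

test_that("frame stacks and raw tracks round-trip through their text formats", {
  tr <- trajectory(c(3, 4, 5, 6), c(3, 3, 4, 4), dt_s = 0.1)
  rf <- render_frames(tr, calibration(2), noise_sd = 3,
                      frame_dims = c(25, 25), seed = 2)
  d <- withr::local_tempdir()
  write_pgm_stack(rf$stack, file.path(d, "stack"))
  back <- read_pgm_stack(file.path(d, "stack"), frame_interval_s = 0.1)
  expect_equal(back$frames, rf$stack$frames)

  rt <- track_stack(rf$stack, 128)
  rt$x_px[2] <- NA; rt$y_px[2] <- NA
  f <- file.path(d, "track.csv")
  write_raw_track(rt, f)
  rt2 <- read_raw_track(f)
  expect_equal(rt2$x_px, rt$x_px)
  expect_equal(attr(rt2, "frame_interval_s"), 0.1)

  # frame_stack invariants
  expect_error(frame_stack(list(matrix(0L, 2, 2), matrix(0L, 3, 2)), 0.1),
               class = "ek_invalid_input")
  expect_warning(frame_stack(list(matrix(0L, 2, 2))), "defaulting to 1/30")
})
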