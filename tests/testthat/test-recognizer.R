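cfgr <- run_config()

test_that("a uniform white frame is invalid with no component", {
  bn <- binarize_frame(matrix(1, 100, 100), cfgr)
  expect_false(bn$valid)
  expect_equal(bn$reason, "no_component")
})

test_that("binarized area matches the rendered silhouette", {
  pose <- straight_pose(4.34)
  ps <- series_from_poses(list(pose))
  rd <- render_frames(ps, output_dir = NULL)
  bn <- binarize_frame(rd$frames[[1]], cfgr)
  expect_true(bn$valid)
  # analytic capsule: (L - w) * w + pi (w/2)^2
  area_true <- (4.34 - 0.8) * 0.8 + pi * 0.4^2
  expect_rel_equal(bn$area_mm2, area_true, 0.02)
})

test_that("small specks are removed, keeping exactly the worm", {
  ps <- series_from_poses(list(straight_pose(4.34)))
  img <- render_frames(ps, output_dir = NULL)$frames[[1]]
  worm_px <- sum(img == 0)
  img[5:6, 5:6] <- 0        # 4-px speck
  img[200, 30:32] <- 0      # 3-px speck
  img[100:101, 220] <- 0    # 2-px speck
  bn <- binarize_frame(img, cfgr)
  expect_true(bn$valid)
  expect_equal(sum(bn$mask), worm_px)
})

test_that("a straight bar thins to its full-length centerline", {
  m <- matrix(FALSE, 40, 120)
  m[18:22, 11:110] <- TRUE
  sk <- extract_skeleton(m, cfgr)
  expect_true(sk$ok)
  expect_lt(abs(sk$arc_length - 99), 2)
  # collinear: y spread below a pixel
  expect_lt(diff(range(sk$path[, 2])), 1)
})

test_that("a disk has no elongated axis and fails with reason topology", {
  m <- matrix(FALSE, 80, 80)
  for (i in 1:80) for (j in 1:80)
    if ((i - 40)^2 + (j - 40)^2 <= 25^2) m[i, j] <- TRUE
  sk <- extract_skeleton(m, cfgr)
  expect_false(sk$ok)
  expect_equal(sk$reason, "topology")
})

test_that("a rendered curved worm's skeleton length matches its midline", {
  th <- seq(-pi / 3, pi / 3, length.out = 13)
  pts <- resample_midline(cbind(4 * cos(th), 4 * sin(th)), 13)
  L_true <- sum(sqrt(rowSums(diff(pts)^2)))
  ps <- series_from_poses(list(pts))
  rd <- render_frames(ps, output_dir = NULL)
  bn <- binarize_frame(rd$frames[[1]], cfgr)
  sk <- extract_skeleton(bn$mask, cfgr)
  expect_true(sk$ok)
  expect_rel_equal(sk$arc_length * cfgr$mm_per_pixel, L_true, 0.05)
})

test_that("resampling divides any path into 12 equal arc segments", {
  expect_error(resample_midline(cbind(1:5, 1:5), n = 1), "n must be")
  # straight path of length 12: points at 0, 1, ..., 12
  p <- resample_midline(cbind(seq(0, 12, by = 0.25), 0), 13)
  expect_equal(p[, 1], 0:12, tolerance = 1e-9)
  expect_equal(p[, 2], rep(0, 13), tolerance = 1e-12)
  # semicircle: equal arc spacing implies equal chords of 2 r sin(pi/24)
  r <- 40
  th <- seq(0, pi, length.out = 3000)
  sc <- resample_midline(cbind(r * cos(th), r * sin(th)), 13)
  chords <- sqrt(rowSums(diff(sc)^2))
  expect_lt(max(chords) / min(chords), 1.001)
  expect_rel_equal(mean(chords), 2 * r * sin(pi / 24), 0.001)
})

test_that("resampling matches a brute-force arc-length oracle", {
  worst <- 0
  for (seed in 1:100) {
    path <- random_smooth_curve(seed)
    a <- resample_midline(path, 13)
    b <- oracle_resample(path, 13)
    worst <- max(worst, max(sqrt(rowSums((a - b)^2))))
  }
  expect_lt(worst, 0.5)
})

test_that("pixel offsets map to plate coordinates through the stage", {
  calib <- calibration_info(0.05)
  fs <- c(240, 240)
  ctr <- matrix(c((fs[1] + 1) / 2, (fs[2] + 1) / 2), 1)
  expect_equal(as.numeric(to_plate_coords(ctr, c(0, 0), calib, fs)),
               c(0, 0))
  p1 <- to_plate_coords(ctr + c(10, 4), c(0, 0), calib, fs)
  expect_equal(as.numeric(p1), c(0.5, -0.2))  # y axis flips
  p2 <- to_plate_coords(ctr + c(10, 4), c(2, 0), calib, fs)
  expect_equal(p2[1] - p1[1], 2)
  expect_equal(p2[2], p1[2])
})

test_that("orientation restores a randomly flipped series", {
  sim <- simulate_crawl(quick_config(duration = 20, seed = 6))
  s <- sim$series
  P <- as.matrix(s[, 5:30])
  set.seed(99)
  flip <- runif(nrow(P)) < 0.5
  Pf <- P
  for (i in which(flip)) {
    m <- matrix(P[i, ], ncol = 2, byrow = TRUE)
    Pf[i, ] <- as.vector(t(m[13:1, ]))
  }
  scr <- pose_series(s$frame, s$time, Pf, frame_rate = 7.5)
  out <- orient_head_tail(scr)
  Po <- as.matrix(out[, 5:30])
  # endpoint tracks continuous: mean frame-to-frame endpoint jump below
  # one segment length
  jump <- sqrt(rowSums((Po[-1, 1:2] - Po[-nrow(Po), 1:2])^2))
  expect_lt(mean(jump), mean(body_length(out)) / 12)
  # head label equals the true head in >= 95% of frames
  d_head <- sqrt(rowSums((Po[, 1:2] - P[, 1:2])^2))
  d_tail <- sqrt(rowSums((Po[, 1:2] - P[, 25:26])^2))
  expect_gte(mean(d_head < d_tail), 0.95)
  expect_gt(attr(out, "orientation_confidence"), 0)
})

test_that("a single-frame series gets zero orientation confidence", {
  s <- series_from_poses(list(straight_pose(4.3)))
  out <- orient_head_tail(s)
  expect_equal(attr(out, "orientation_confidence"), 0)
})

test_that("render-recognize round trip recovers the noiseless midline", {
  sim <- simulate_crawl(quick_config(duration = 20, seed = 7))
  td <- withr::local_tempdir()
  rd <- render_frames(sim$series, output_dir = td)
  rec <- recognize_video(td, rd$stage_log, cfgr)
  expect_s3_class(rec, "pose_series")
  v <- rec$valid
  expect_gt(mean(v), 0.95)
  P0 <- as.matrix(sim$series[, 5:30])[v, ]
  P1 <- as.matrix(rec[, 5:30])[v, ]
  # per-frame midline RMSE below 0.1 mm
  expect_lt(sqrt(mean((P0 - P1)^2)), 0.1)
  # center-point trajectory within 0.05 mm RMSE
  c0 <- point_xy(sim$series, 7)[v, ]; c1 <- point_xy(rec, 7)[v, ]
  expect_lt(sqrt(mean((c0 - c1)^2)), 0.05)
  # body length within 5%
  expect_rel_equal(mean(body_length(rec)[v]),
                   mean(body_length(sim$series)[v]), 0.05)
  # equal-spacing invariant on every valid pose
  for (i in which(v)) {
    d <- sqrt(rowSums(diff(pose_matrix(rec, i))^2))
    expect_lt(max(d) / min(d), 1.1)
  }
})

test_that("recognizing every 2nd frame reproduces the same geometry", {
  sim <- simulate_crawl(quick_config(duration = 8, seed = 12))
  rd <- render_frames(sim$series, output_dir = NULL)
  rec_full <- recognize_video(rd$frames, rd$stage_log, cfgr)
  keep <- seq(1, nrow(sim$series), by = 2)
  log_half <- rd$stage_log[keep, ]
  log_half$frame_index <- seq_along(keep)
  cfg_half <- run_config(frame_rate = cfgr$frame_rate / 2)
  rec_half <- recognize_video(rd$frames[keep], log_half, cfg_half)
  P_full <- as.matrix(rec_full[keep, 5:30])
  P_half <- as.matrix(rec_half[, 5:30])
  ok <- rec_full$valid[keep] & rec_half$valid
  expect_gt(mean(ok), 0.9)
  # per-frame geometry is identical; the global head/tail label is a
  # whole-series decision and may differ, so align orientation first
  flip26 <- function(v) as.vector(t(matrix(v, ncol = 2,
                                           byrow = TRUE)[13:1, ]))
  d_keep <- mean(abs(P_half[ok, ] - P_full[ok, ]))
  d_flip <- mean(abs(t(apply(P_half[ok, , drop = FALSE], 1, flip26)) -
                     P_full[ok, ]))
  expect_lt(min(d_keep, d_flip), 1e-10)
})

test_that("stage-log gaps of more than two frames invalidate frames", {
  sim <- simulate_crawl(quick_config(duration = 6, seed = 4))
  rd <- render_frames(sim$series, output_dir = NULL)
  log2 <- rd$stage_log[-(10:14), ]  # 5-frame hole
  rec <- recognize_video(rd$frames, log2, cfgr)
  expect_true(all(rec$reason[10:14] == "stage_gap"))
  expect_true(all(!rec$valid[10:14]))
  log3 <- rd$stage_log[-(20:21), ]  # 2-frame hole: interpolated
  rec3 <- recognize_video(rd$frames, log3, cfgr)
  expect_true(all(rec3$valid[20:21]))
})
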