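test_that("sine-wave length yields minima spaced one period apart", {
  fps <- 7.5; T <- 1.6
  t <- seq(0, 30, by = 1 / fps)
  len <- 4.3 + 0.25 * sin(2 * pi * t / T)
  ext <- length_extrema(len, t, min_prominence = 0.13, frame_rate = fps,
                        smooth_window = 0)
  mins <- ext$time[ext$type == "min"]
  expect_gt(length(mins), 15)
  expect_lt(max(abs(diff(mins) - T)), 1.5 / fps)
  # strictly alternating
  expect_true(all(ext$type[-1] != ext$type[-nrow(ext)]))
})

test_that("constant or sub-prominence signals yield no extrema", {
  fps <- 7.5
  t <- seq(0, 20, by = 1 / fps)
  expect_equal(nrow(length_extrema(rep(4.3, length(t)), t, 0.13, fps)), 0)
  set.seed(1)
  weak <- 4.3 + 0.04 * sin(2 * pi * t / 1.6) + rnorm(length(t), 0, 0.005)
  ext <- length_extrema(weak, t, min_prominence = 0.13, frame_rate = fps,
                        smooth_window = 0)
  expect_equal(nrow(ext), 0)
})

test_that("prominence filtering matches an exhaustive scan oracle", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- 300
    t <- seq_len(n) / 7.5
    sig <- 4.3 +
      0.3 * sin(2 * pi * t / runif(1, 1, 4)) +
      0.15 * sin(2 * pi * t / runif(1, 4, 12) + runif(1, 0, 6)) +
      cumsum(rnorm(n, 0, 0.01))
    prom <- runif(1, 0.05, 0.3)
    got <- length_extrema(sig, t, prom, 7.5, smooth_window = 0)
    want <- oracle_extrema(sig, prom)
    expect_equal(got$index, want$index,
                 label = sprintf("seed %d indices", seed))
    expect_equal(got$type, want$type,
                 label = sprintf("seed %d types", seed))
  }
})

test_that("a pure pause classifies as 0% striding", {
  sim <- simulate_crawl(quick_config(duration = 30, seed = 3, noise = 0,
                                     time_striding_target = 0))
  sa <- stride_analysis(sim$series, run_config())
  expect_equal(sum(sa$striding), 0)
  expect_equal(nrow(sa$strides), 0)
  expect_equal(nrow(sa$runs), 0)
})

test_that("one noiseless cycle with travel gives exactly one stride", {
  fps <- 10; T <- 1.6
  t <- seq(0, 6, by = 1 / fps)
  # one full min-max-min excursion in the middle; gentle slopes outside
  # place the two minima in the interior of the series
  len <- rep(4.085, length(t))
  len[t < 2] <- 4.085 + 0.1 * (2 - t[t < 2])
  after <- t > 2 + T
  len[after] <- 4.085 + 0.1 * (t[after] - 2 - T)
  cyc <- t >= 2 & t <= 2 + T
  len[cyc] <- 4.085 + 0.51 * sin(pi * (t[cyc] - 2) / T)^2
  x <- rep(0, length(t))
  x[t > 2] <- 0.6 * (pmin(t[t > 2], 2 + T) - 2)  # advances during cycle
  s <- series_from_poses(lapply(seq_along(t), function(i)
    straight_pose(len[i], cx = x[i])), fps)
  cfg <- run_config(frame_rate = fps, smooth_length = 0)
  sa <- stride_analysis(s, cfg)
  expect_equal(nrow(sa$strides), 1)
  expect_rel_equal(sa$strides$duration, T, 0.15)
  expect_rel_equal(mean(sa$striding), T / max(t), 0.2)
})

test_that("triangle-wave length gives exact phase rates", {
  fps <- 10
  t_e <- 0.6; t_c <- 0.9; dL <- 0.5
  T <- t_e + t_c
  t <- seq(0, 12, by = 1 / fps)
  phase <- (t %% T)
  len <- ifelse(phase <= t_e, 4.1 + dL * phase / t_e,
                4.1 + dL * (1 - (phase - t_e) / t_c))
  s <- series_from_lengths(len, speed = 0.6, frame_rate = fps)
  cfg <- run_config(frame_rate = fps, smooth_length = 0)
  sa <- stride_analysis(s, cfg)
  expect_gt(nrow(sa$strides), 4)
  expect_equal(sa$strides$extension_rate,
               rep(dL / t_e, nrow(sa$strides)), tolerance = 1e-9)
  expect_equal(sa$strides$contraction_rate,
               rep(dL / t_c, nrow(sa$strides)), tolerance = 1e-9)
  expect_equal(sa$strides$length_max - sa$strides$length_min,
               rep(dL, nrow(sa$strides)), tolerance = 1e-9)
})

test_that("a stride straddling an invalid-frame gap is dropped", {
  sim <- simulate_crawl(quick_config(duration = 40, seed = 5,
                                     time_striding_target = 1,
                                     run_turn_sd = 0,
                                     head_sweep_amplitude = 0))
  s <- sim$series
  sa0 <- stride_analysis(s, run_config())
  n0 <- nrow(sa0$strides)
  expect_gt(n0, 10)
  # invalidate two frames inside the 5th detected stride
  k <- which(s$time > sa0$strides$t_start[5] &
             s$time < sa0$strides$t_end[5])[2:3]
  s$valid[k] <- FALSE
  s[k, 5:30] <- NA_real_
  sa1 <- stride_analysis(s, run_config())
  expect_lt(nrow(sa1$strides), n0)
  # no detected stride spans the gap
  expect_false(any(sa1$strides$t_start < s$time[k[1]] &
                   sa1$strides$t_end > s$time[k[2]]))
})

test_that("runs merge, split and conserve stride counts", {
  cfgr <- run_config()
  # uninterrupted striding: one run holding every stride
  sim1 <- simulate_crawl(quick_config(duration = 40, seed = 2,
                                      time_striding_target = 1,
                                      run_turn_sd = 0,
                                      head_sweep_amplitude = 0))
  sa1 <- stride_analysis(sim1$series, cfgr)
  expect_equal(nrow(sa1$runs), 1)
  expect_equal(sa1$runs$stride_count, nrow(sa1$strides))
  # three widely separated blocks: three runs, counts conserved
  sim3 <- simulate_crawl(quick_config(duration = 120, seed = 14,
                                      time_striding_target = 0.5,
                                      n_runs_target = 3))
  sa3 <- stride_analysis(sim3$series, cfgr)
  expect_equal(nrow(sa3$runs), 3)
  expect_equal(sum(sa3$runs$stride_count), nrow(sa3$strides))
  # targeted run count recovered
  sim4 <- simulate_crawl(quick_config(duration = 180, seed = 25,
                                      time_striding_target = 0.6,
                                      n_runs_target = 4))
  sa4 <- stride_analysis(sim4$series, cfgr)
  expect_equal(nrow(sa4$runs), 4)
})

test_that("recovered striding fraction tracks the generator labels", {
  sim <- simulate_crawl(quick_config(duration = 240, seed = 10,
                                     noise = 0.01))
  sa <- stride_analysis(sim$series, run_config())
  expect_lt(abs(mean(sa$striding) -
                mean(sim$truth$labels$striding)), 0.05)
})
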