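test_that("a noiseless crawler summary recovers every true parameter", {
  sim <- simulate_crawl(quick_config(duration = 60, seed = 3))
  sm <- summarize_video(sim$series, run_config())
  tru <- sim$truth$summary
  for (p in parameter_names()) {
    if (is.na(tru[[p]])) next
    if (tru[[p]] == 0) {
      expect_lt(abs(sm[[p]]), 0.02)
    } else {
      expect_rel_equal(sm[[p]], tru[[p]], 0.1)
    }
  }
  expect_false(sm$error)
  expect_equal(sm$n_valid_frames, nrow(sim$series))
})

test_that("an all-pause video reports missing stride parameters", {
  sim <- simulate_crawl(quick_config(duration = 30, seed = 6,
                                     time_striding_target = 0))
  sm <- summarize_video(sim$series, run_config())
  expect_equal(sm$time_striding, 0)
  expect_true(is.na(sm$stride_duration))
  expect_true(is.na(sm$stride_distance))
  expect_true(is.na(sm$body_length_contracted))
  expect_lt(sm$distance, 1)
  expect_equal(sm$stride_count, 0)
})

test_that("stride counts agree with the time-striding identity", {
  # the identity stride_count ~ 60 * TimeStriding / StrideDuration holds
  # for the wild-type means (60 * 0.76 / 1.61 = 28.3 vs 29.91 printed)
  expect_lt(abs(60 * 0.76 / 1.61 - 29.91) / 29.91, 0.15)
  for (seed in c(3, 11, 27)) {
    sim <- simulate_crawl(quick_config(duration = 120, seed = seed,
                                       noise = 0.01))
    sm <- summarize_video(sim$series, run_config())
    ident <- 60 * sm$time_striding / sm$stride_duration
    expect_rel_equal(sm$stride_count, ident, 0.15)
  }
})

test_that("summaries expose overall, inside and outside variants", {
  # park the animal so part of the session is in the ring zone
  sim <- simulate_crawl(quick_config(duration = 120, seed = 35))
  sm <- summarize_video(sim$series, run_config())
  expect_true(all(paste0(rep(c("speed", "time_striding"), each = 2),
                         c("_inside", "_outside")) %in% names(sm)))
  ti <- sm$time_inside
  if (is.finite(ti) && ti > 0 && ti < 1) {
    # overall lies between the inside and outside variants
    lo <- min(sm$speed_inside, sm$speed_outside)
    hi <- max(sm$speed_inside, sm$speed_outside)
    expect_gte(sm$speed, lo - 1e-9)
    expect_lte(sm$speed, hi + 1e-9)
  }
})

test_that("coefficient of variation follows its definition", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), 100 * sqrt(2) / 3,
               tolerance = 1e-9)
  expect_equal(round(coefficient_of_variation(c(2, 4)), 2), 47.14)
  expect_equal(coefficient_of_variation(c(-2, -2)), 0)
  expect_true(is.na(coefficient_of_variation(c(5))))
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))
  # scale invariance
  set.seed(8)
  v <- rlnorm(20)
  expect_equal(coefficient_of_variation(3.7 * v),
               coefficient_of_variation(v), tolerance = 1e-9)
})

test_that("batch processing is deterministic and skips corrupt files", {
  td <- withr::local_tempdir()
  for (k in 1:3) {
    sim <- simulate_crawl(quick_config(duration = 20, seed = k))
    write_points(sim$series, file.path(td, sprintf("vid%02d.tsv", k)))
  }
  writeLines(c("frame_index\ttime_s", "1\t0", "garbage"),
             file.path(td, "broken.tsv"))
  suppressMessages({
    tab <- batch_process(td, config = run_config())
  })
  expect_equal(nrow(tab), 3)
  expect_equal(tab$video_id, c("vid01", "vid02", "vid03"))
  expect_equal(attr(tab, "skipped"), "broken.tsv")
  suppressMessages({
    tab2 <- batch_process(td, config = run_config())
  })
  expect_equal(tab, tab2, ignore_attr = TRUE)
  expect_warning(batch_process(withr::local_tempdir()), "no points files")
})

test_that("control normalization cancels shared day effects", {
  set.seed(5)
  base <- data.frame(
    video_id = sprintf("v%02d", 1:12),
    genotype = rep(c("control", "mut"), each = 6),
    date = rep(c("d1", "d2"), 6),
    speed = runif(12, 0.4, 0.8),
    stride_distance = runif(12, 0.7, 1.0))
  params <- c("speed", "stride_distance")
  nrm <- normalize_by_control(base, "control", params)
  # test equal to control mean -> normalized 1
  cm <- tapply(base$speed[base$genotype == "control"],
               base$date[base$genotype == "control"], mean)
  i <- which(base$genotype == "mut")[1]
  manual <- base$speed[i] / cm[[base$date[i]]]
  expect_equal(nrm$speed[i], manual, tolerance = 1e-12)
  # multiplying every same-date value by c > 0 leaves results unchanged
  scaled <- base
  for (d in unique(base$date)) {
    cc <- if (d == "d1") 3.2 else 0.45
    sel <- scaled$date == d
    scaled$speed[sel] <- scaled$speed[sel] * cc
    scaled$stride_distance[sel] <- scaled$stride_distance[sel] * cc
  }
  nrm2 <- normalize_by_control(scaled, "control", params)
  expect_equal(nrm2$speed, nrm$speed, tolerance = 1e-12)
  expect_equal(nrm2$stride_distance, nrm$stride_distance,
               tolerance = 1e-12)
})

test_that("self-normalized control profiles are identically one", {
  set.seed(6)
  base <- data.frame(
    video_id = sprintf("v%02d", 1:8),
    genotype = "control",
    date = rep(c("d1", "d2"), 4),
    speed = runif(8, 0.4, 0.8),
    time_striding = runif(8, 0.6, 0.9))
  params <- c("speed", "time_striding")
  nrm <- normalize_by_control(base, "control", params)
  pm <- profile_matrix(nrm, params)
  expect_equal(as.numeric(pm["control", ]), c(1, 1), tolerance = 1e-12)
  pc <- profile_correlation(rbind(pm, other = pm["control", ]))
  expect_equal(pc["control", "other"], 1)
})

test_that("perturbed generative parameters shift only their own profile", {
  cfg_a <- quick_config(duration = 90, seed = 1)
  rows <- list()
  for (k in 1:3) {
    sim <- simulate_crawl(quick_config(duration = 90, seed = k))
    sm <- summarize_video(sim$series, run_config(),
                          metadata = list(video_id = paste0("c", k),
                                          genotype = "control",
                                          date = "d1"))
    rows[[length(rows) + 1]] <- sm
  }
  # "mutant": 30% shorter strides, same period
  for (k in 1:3) {
    sim <- simulate_crawl(quick_config(duration = 90, seed = 10 + k,
                                       stride_distance = 0.89 * 0.7))
    sm <- summarize_video(sim$series, run_config(),
                          metadata = list(video_id = paste0("m", k),
                                          genotype = "mut",
                                          date = "d1"))
    rows[[length(rows) + 1]] <- sm
  }
  tab <- do.call(rbind, rows)
  params <- c("body_length", "stride_duration", "stride_distance",
              "time_striding")
  nrm <- normalize_by_control(tab, "control", params)
  pm <- profile_matrix(nrm, params)
  # perturbed parameter shows the configured ratio; others stay near 1
  expect_rel_equal(pm["mut", "stride_distance"], 0.7, 0.1)
  expect_lt(abs(pm["mut", "body_length"] - 1), 0.05)
  expect_lt(abs(pm["mut", "stride_duration"] - 1), 0.1)
})
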