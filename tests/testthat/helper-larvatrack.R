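# Shared fixtures and independent oracles. All fixtures are built in code.

# short Canton-S-anchored configuration for fast tests
quick_config <- function(duration = 30, seed = 1, noise = 0, ...) {
  sim_config(duration = duration, rng_seed = seed,
             noise_sd_position = noise, ...)
}

# random plausible crawler configurations for property tests
random_sim_config <- function(seed) {
  set.seed(seed)
  ml <- runif(1, 3, 5.5)
  sim_config(mean_length = ml,
             length_amplitude = runif(1, 0.12, min(0.3, 0.45 * ml / 2)),
             stride_period = runif(1, 0.8, 3),
             stride_distance = runif(1, 0.5, 1.3),
             time_striding_target = runif(1, 0.4, 0.95),
             n_runs_target = sample(2:8, 1),
             head_sweep_amplitude = runif(1, 30, 80),
             duration = 180, noise_sd_position = 0.01, rng_seed = seed)
}

# a straight horizontal worm of length L with center at (cx, cy)
straight_pose <- function(L = 4.32, cx = 0, cy = 0) {
  x <- seq(cx + L / 2, cx - L / 2, length.out = 13)
  cbind(x = x, y = rep(cy, 13))
}

# build a pose series from a list of 13x2 matrices
series_from_poses <- function(poses, frame_rate = 7.5) {
  n <- length(poses)
  P <- t(vapply(poses, function(p) as.vector(t(p)), numeric(26)))
  pose_series(frame = seq_len(n), time = (seq_len(n) - 1) / frame_rate,
              points = P, frame_rate = frame_rate)
}

# a series whose body length follows `lengths` while the center advances
# at constant speed along +x (straight horizontal worm)
series_from_lengths <- function(lengths, speed = 0.6, frame_rate = 7.5) {
  n <- length(lengths)
  t <- (seq_len(n) - 1) / frame_rate
  series_from_poses(lapply(seq_len(n), function(i)
    straight_pose(lengths[i], cx = speed * t[i])), frame_rate)
}

# independent oracle: arc-length resampling by dense subdivision
oracle_resample <- function(path, n = 13, step = 1e-3) {
  d <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(d))
  total <- cum[length(cum)]
  s_dense <- seq(0, total, by = step)
  xd <- approx(cum, path[, 1], xout = s_dense, ties = "ordered")$y
  yd <- approx(cum, path[, 2], xout = s_dense, ties = "ordered")$y
  targets <- total * (seq_len(n) - 1) / (n - 1)
  idx <- vapply(targets, function(s) which.min(abs(s_dense - s)),
                integer(1))
  cbind(xd[idx], yd[idx])
}

# independent oracle: exhaustive local-extremum scan with prominence
# filtering and alternation by repeated removal of the weaker neighbor
oracle_extrema <- function(s, min_prom) {
  n <- length(s)
  is_max <- is_min <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (s[i] > s[i - 1] && s[i] > s[i + 1]) is_max[i] <- TRUE
    if (s[i] < s[i - 1] && s[i] < s[i + 1]) is_min[i] <- TRUE
  }
  prom_of <- function(i, sig) {
    h <- sig[i]
    lo_l <- h; j <- i - 1
    while (j >= 1 && sig[j] <= h) { lo_l <- min(lo_l, sig[j]); j <- j - 1 }
    if (j < 1) lo_l <- min(sig[1:i])
    lo_r <- h; j <- i + 1
    while (j <= length(sig) && sig[j] <= h) {
      lo_r <- min(lo_r, sig[j]); j <- j + 1
    }
    if (j > length(sig)) lo_r <- min(sig[i:length(sig)])
    h - max(lo_l, lo_r)
  }
  keep_max <- which(is_max)[vapply(which(is_max), function(i)
    prom_of(i, s) >= min_prom, logical(1))]
  keep_min <- which(is_min)[vapply(which(is_min), function(i)
    prom_of(i, -s) >= min_prom, logical(1))]
  df <- rbind(
    if (length(keep_max)) data.frame(type = "max", index = keep_max),
    if (length(keep_min)) data.frame(type = "min", index = keep_min))
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(type = character(0), index = integer(0)))
  df <- df[order(df$index), , drop = FALSE]
  repeat {
    same <- which(df$type[-1] == df$type[-nrow(df)])
    if (!length(same)) break
    k <- same[1]
    a <- df$index[k]; b <- df$index[k + 1]
    worse <- if (df$type[k] == "max") {
      if (s[a] >= s[b]) k + 1 else k
    } else {
      if (s[a] <= s[b]) k + 1 else k
    }
    df <- df[-worse, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# random smooth open curve in pixel coordinates (no self-intersection on
# the scales used): integrated random headings
random_smooth_curve <- function(seed, n = 400) {
  set.seed(seed)
  dth <- stats::filter(rnorm(n, 0, 0.08), rep(1 / 15, 15), sides = 2)
  dth[is.na(dth)] <- 0
  th <- cumsum(dth) + runif(1, 0, 2 * pi)
  cbind(cumsum(cos(th)), cumsum(sin(th)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(is.finite(actual) && is.finite(expected) &&
              abs(actual - expected) <= tol * abs(expected),
              label = sprintf("%.4f vs %.4f (rel tol %.2g)",
                              actual, expected, tol))
}
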