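# Synthetic peristaltic crawler.
#
# Striding model: the larva is a straight 13-point midline of oscillating
# length. During one stride cycle of period T the length rises linearly from
# mean - a to mean + a over the extension fraction f of the cycle, then
# falls back; the tail is anchored while the head extends, and catches up
# while the head holds during contraction. A uniform forward drift makes the
# net center advance per cycle equal the configured stride distance.
# Non-striding bouts hold position while the body relaxes toward mean
# length and the head sweeps sinusoidally; heading changes occur between
# strides (small) and after pauses (up to the sweep amplitude).

# Build the alternating pause/run schedule. Runs carry an integer number of
# strides so stride boundaries nest exactly inside run boundaries.
build_schedule <- function(cfg) {
  T <- cfg$stride_period
  dur <- cfg$duration
  target <- cfg$time_striding_target
  if (target >= 1) {
    n_str <- floor(dur / T)
  } else {
    n_str <- round(target * dur / T)
  }
  if (n_str == 0) {
    return(data.frame(type = "pause", t0 = 0, dur = dur, run = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  pause_total <- dur - n_str * T
  min_gap <- 1.5  # s; interior pauses must be long enough to break a run
  n_runs <- min(cfg$n_runs_target, n_str)
  if (n_runs > 1 && pause_total < min_gap * (n_runs - 1))
    n_runs <- max(1L, floor(pause_total / min_gap) + 1L)
  # strides per run
  per_run <- rep(n_str %/% n_runs, n_runs)
  extra <- n_str %% n_runs
  if (extra > 0) {
    ix <- if (n_runs == 1) 1L else sample.int(n_runs, extra)
    per_run[ix] <- per_run[ix] + 1L
  }
  # pause durations: reserve min_gap for interior gaps, distribute the rest
  # with exponential weights over all n_runs + 1 gaps (memoryless bouts)
  gaps <- rep(0, n_runs + 1)
  if (n_runs > 1) gaps[2:n_runs] <- min_gap
  rest <- pause_total - sum(gaps)
  if (rest > 0) {
    w <- rexp(n_runs + 1)
    gaps <- gaps + rest * w / sum(w)
  }
  ev <- list()
  t <- 0
  add <- function(type, d, run) {
    if (d <= 0) return()
    ev[[length(ev) + 1]] <<- data.frame(type = type, t0 = t, dur = d,
                                        run = run, stringsAsFactors = FALSE)
    t <<- t + d
  }
  for (r in seq_len(n_runs)) {
    add("pause", gaps[r], NA_integer_)
    for (s in seq_len(per_run[r])) add("stride", T, r)
  }
  add("pause", gaps[n_runs + 1], NA_integer_)
  do.call(rbind, ev)
}

rotate_vec <- function(u, phi) {
  c(cos(phi) * u[1] - sin(phi) * u[2], sin(phi) * u[1] + cos(phi) * u[2])
}

#' Simulate a crawling larva with ground truth
#'
#' Generates a plate-frame 13-point midline series for one synthetic
#' session, together with the true per-frame striding labels, stride and
#' run boundaries, and the true per-video parameter vector. The trajectory
#' reflects off the confinement ring; identical seeds give bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return A list with elements \code{series} (a [pose_series()]) and
#'   \code{truth} (class \code{ground_truth}: per-frame labels, stride and
#'   run tables, and a one-row \code{summary} in the per-video parameter
#'   schema).
#' @examples
#' sim <- simulate_crawl(sim_config(duration = 30))
#' sim$truth$summary$stride_duration
#' @export
simulate_crawl <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$rng_seed)
  fps <- cfg$frame_rate
  n <- max(1L, round(cfg$duration * fps))
  tvec <- (seq_len(n) - 1) / fps

  sched <- build_schedule(cfg)
  a <- cfg$length_amplitude
  dL <- 2 * a
  L_min <- cfg$mean_length - a
  L_mean <- cfg$mean_length
  f <- cfg$extension_fraction
  T <- cfg$stride_period
  d_extra <- cfg$stride_distance - dL
  r_reflect <- cfg$arena_radius - cfg$ring_width / 2
  A_rad <- cfg$head_sweep_amplitude * pi / 180

  # initial state: somewhere well inside the ring, random heading
  r0 <- 0.4 * (cfg$arena_radius - cfg$ring_width) * sqrt(runif(1))
  ang0 <- runif(1, 0, 2 * pi)
  theta <- runif(1, 0, 2 * pi)
  cen <- r0 * c(cos(ang0), sin(ang0))

  P <- matrix(NA_real_, n, 26)
  striding <- logical(n)
  length_true <- numeric(n)
  phi_true <- numeric(n)

  len_fun <- function(tau) {
    ifelse(tau <= f, L_min + dL * tau / f, L_min + dL * (1 - tau) / (1 - f))
  }
  # cumulative advance of the body center within a stride cycle (phase
  # tau): tail-anchored extension pushes the center forward at dL/2 per
  # extension phase, the contraction wave carries the rest, and a uniform
  # drift tops the cycle advance up to the configured stride distance.
  # The resulting center speed is constant at stride_distance / T for the
  # default symmetric cycle. Rotations act about the center, so heading
  # changes never displace it.
  adv_fun <- function(tau) {
    b <- ifelse(tau <= f, 0, dL * (tau - f) / (1 - f))
    b + d_extra * tau + (len_fun(tau) - L_min) / 2
  }

  stride_rows <- list()
  prev_type <- NA_character_
  for (e in seq_len(nrow(sched))) {
    type <- sched$type[e]
    t0 <- sched$t0[e]
    dur_e <- sched$dur[e]
    next_type <- if (e < nrow(sched)) sched$type[e + 1] else NA_character_
    idx <- which(tvec >= t0 - 1e-9 & tvec < t0 + dur_e - 1e-9)
    if (type == "stride") {
      # heading at stride end; reflect off the ring if the step would exit
      delta <- rnorm(1, 0, cfg$run_turn_sd * pi / 180)
      u_now <- c(cos(theta), sin(theta))
      cen_end <- cen + cfg$stride_distance * u_now
      if (sqrt(sum(cen_end^2)) > r_reflect) {
        nhat <- cen / max(sqrt(sum(cen^2)), 1e-9)
        u_ref <- u_now - 2 * sum(u_now * nhat) * nhat
        if (sum(u_ref * nhat) > 0) u_ref <- -nhat
        theta <- atan2(u_ref[2], u_ref[1])
        delta <- 0
      }
      theta_end <- theta + delta
      tau <- (tvec[idx] - t0) / T
      tau_grid <- c(tau, 1)
      adv <- adv_fun(tau_grid)
      d_adv <- diff(c(0, adv))
      th_grid <- theta + tau_grid * (theta_end - theta)
      cen_cur <- cen
      for (k in seq_along(tau_grid)) {
        th_k <- th_grid[k]
        cen_cur <- cen_cur + d_adv[k] * c(cos(th_k), sin(th_k))
        if (k <= length(idx)) {
          i <- idx[k]
          Lk <- len_fun(tau_grid[k])
          tail_k <- cen_cur - (Lk / 2) * c(cos(th_k), sin(th_k))
          P[i, ] <- flatten_pose(make_pose(tail_k, th_k, Lk, 0))
          striding[i] <- TRUE
          length_true[i] <- Lk
          phi_true[i] <- 0
        }
      }
      cen <- cen_cur
      theta <- theta_end
      stride_rows[[length(stride_rows) + 1]] <-
        data.frame(t_start = t0, t_end = t0 + T, run = sched$run[e])
    } else {
      # pause: anchored tail, length relaxes toward mean between short
      # stationary flats at L_min next to the adjacent strides (the animal
      # settles before initiating the next stride), head sweeps
      L_start <- if (identical(prev_type, "stride")) L_min else L_mean
      g1 <- if (identical(prev_type, "stride")) min(0.3, dur_e / 4) else 0
      g2 <- if (identical(next_type, "stride")) min(0.3, dur_e / 4) else 0
      mid <- max(dur_e - g1 - g2, 0)
      r_up <- if (L_start < L_mean) min(0.4, mid / 3) else 0
      r_dn <- if (identical(next_type, "stride")) min(0.4, mid / 3) else 0
      trel <- tvec[idx] - t0
      Lp <- rep(L_mean, length(idx))
      if (r_up > 0) {
        m <- trel >= g1 & trel < g1 + r_up
        Lp[m] <- L_start + (L_mean - L_start) * (trel[m] - g1) / r_up
      }
      if (g1 > 0) Lp[trel < g1] <- L_start
      if (r_dn > 0) {
        m <- trel > dur_e - g2 - r_dn & trel <= dur_e - g2
        Lp[m] <- L_mean -
          (L_mean - L_min) * (trel[m] - (dur_e - g2 - r_dn)) / r_dn
      }
      if (g2 > 0) Lp[trel > dur_e - g2] <- L_min
      env <- pmin(1, trel / 0.3, (dur_e - trel) / 0.3)
      env[env < 0] <- 0
      phi <- A_rad * sin(2 * pi * trel / cfg$sweep_period) * env
      u_p <- c(cos(theta), sin(theta))
      for (k in seq_along(idx)) {
        i <- idx[k]
        tail_k <- cen - (Lp[k] / 2) * u_p
        P[i, ] <- flatten_pose(make_pose(tail_k, theta, Lp[k], phi[k]))
        striding[i] <- FALSE
        length_true[i] <- Lp[k]
        phi_true[i] <- phi[k]
      }
      if (identical(next_type, "stride") && dur_e > 1) {
        theta <- theta + runif(1, -0.5, 0.5) * A_rad
      }
    }
    prev_type <- type
  }

  # truth tables
  strides <- if (length(stride_rows)) do.call(rbind, stride_rows) else
    data.frame(t_start = numeric(0), t_end = numeric(0), run = integer(0))
  runs <- if (nrow(strides)) {
    agg <- split(strides, strides$run)
    do.call(rbind, lapply(agg, function(d) {
      data.frame(t_start = min(d$t_start), t_end = max(d$t_end),
                 stride_count = nrow(d))
    }))
  } else {
    data.frame(t_start = numeric(0), t_end = numeric(0),
               stride_count = integer(0))
  }
  if (nrow(runs)) {
    runs <- runs[order(runs$t_start), , drop = FALSE]
    rownames(runs) <- NULL
  }

  truth_summary <- simulate_truth_summary(cfg, P, tvec, striding,
                                          length_true, phi_true, runs)

  noise <- if (cfg$noise_sd_position > 0)
    matrix(rnorm(n * 26, 0, cfg$noise_sd_position), n, 26) else 0
  series <- pose_series(frame = seq_len(n), time = tvec, points = P + noise,
                        frame_rate = fps)
  attr(series, "mm_per_pixel") <- NA_real_

  truth <- list(
    labels = data.frame(frame = seq_len(n), time = tvec,
                        striding = striding, length = length_true,
                        head_angle = abs(phi_true) * 180 / pi),
    strides = strides[, c("t_start", "t_end")],
    runs = runs,
    summary = truth_summary,
    config = cfg)
  class(truth) <- "ground_truth"
  list(series = series, truth = truth)
}

# True per-video parameter vector, from the noiseless kinematics and the
# configured stride mechanics.
simulate_truth_summary <- function(cfg, P, tvec, striding, length_true,
                                   phi_true, runs) {
  n <- length(tvec)
  fps <- cfg$frame_rate
  a <- cfg$length_amplitude
  f <- cfg$extension_fraction
  T <- cfg$stride_period
  dur <- cfg$duration
  n_str <- sum(runs$stride_count)
  cen <- P[, c(13, 14)]  # point 7
  step <- sqrt(rowSums((cen[-1, , drop = FALSE] -
                        cen[-n, , drop = FALSE])^2))
  speed_frame <- step * fps
  head_deg <- abs(phi_true) * 180 / pi
  frac_striding <- if (n_str) sum(runs$t_end - runs$t_start) / dur else 0

  dc <- direction_changes(cen, tvec, sample_interval = 1,
                          turn_threshold = 60)
  arena <- arena_geometry(plate_radius = cfg$arena_radius,
                          ring_width = cfg$ring_width)
  ins <- inside_mask(cen, arena, inside_margin = cfg$mean_length / 2)

  data.frame(
    body_length = mean(length_true),
    body_length_contracted = if (n_str) cfg$mean_length - a else NA_real_,
    body_length_extended = if (n_str) cfg$mean_length + a else NA_real_,
    time_head_bending = mean(head_deg > 45),
    time_body_bending = 0,
    time_bending = mean(head_deg > 45),
    speed = mean(speed_frame),
    time_striding = frac_striding,
    speed_striding = if (n_str) cfg$stride_distance / T else NA_real_,
    stride_duration = if (n_str) T else NA_real_,
    stride_distance = if (n_str) cfg$stride_distance else NA_real_,
    contraction_rate = if (n_str) 2 * a / ((1 - f) * T) else NA_real_,
    extension_rate = if (n_str) 2 * a / (f * T) else NA_real_,
    stride_count = n_str / dur * 60,
    run_distance = if (nrow(runs)) mean(runs$stride_count *
                                        cfg$stride_distance) else NA_real_,
    run_duration = if (nrow(runs)) mean(runs$t_end - runs$t_start)
                   else NA_real_,
    run_stride_count = if (nrow(runs)) mean(runs$stride_count) else NA_real_,
    run_count = nrow(runs) / dur * 60,
    distance = sum(step) / dur * 60,
    direction_change = dc$fraction,
    time_inside = ins$fraction)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d frames, %d strides in %d runs, time striding %.3f\n",
    nrow(x$labels), nrow(x$strides), nrow(x$runs),
    x$summary$time_striding))
  invisible(x)
}
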