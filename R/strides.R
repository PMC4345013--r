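# Stride engine: peristalsis cycles are detected as minimum-to-minimum
# intervals of the body-length oscillation, then filtered by period,
# excursion and forward displacement of the body center. Frames inside
# accepted cycles are "striding"; consecutive strides merge into runs.

# local extrema (with plateau handling) of a numeric vector without NAs;
# returns list(max = indices, min = indices)
local_extrema_idx <- function(s) {
  n <- length(s)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  # collapse plateaus: runs of equal consecutive values
  r <- rle(s)
  m <- length(r$values)
  if (m < 3) return(list(max = integer(0), min = integer(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mid <- floor((starts + ends) / 2)
  v <- r$values
  is_max <- is_min <- rep(FALSE, m)
  for (k in 2:(m - 1)) {
    if (v[k] > v[k - 1] && v[k] > v[k + 1]) is_max[k] <- TRUE
    if (v[k] < v[k - 1] && v[k] < v[k + 1]) is_min[k] <- TRUE
  }
  list(max = mid[is_max], min = mid[is_min])
}

# topographic prominence of peaks at `idx` in signal s (no NAs)
peak_prominence <- function(s, idx) {
  vapply(idx, function(i) {
    h <- s[i]
    # walk left to the nearest strictly higher value
    lo_l <- h
    j <- i - 1
    while (j >= 1 && s[j] <= h) { if (s[j] < lo_l) lo_l <- s[j]; j <- j - 1 }
    if (j < 1) lo_l <- min(s[1:i])
    lo_r <- h
    j <- i + 1
    n <- length(s)
    while (j <= n && s[j] <= h) { if (s[j] < lo_r) lo_r <- s[j]; j <- j + 1 }
    if (j > n) lo_r <- min(s[i:n])
    h - max(lo_l, lo_r)
  }, numeric(1))
}

# slope of body length over the interior of one stride phase (25% trimmed
# at each end to exclude the smoothing-rounded extrema); falls back to the
# endpoint difference quotient for very short phases
phase_rate <- function(length_mm, time, ia, ib, fallback) {
  k <- floor(0.25 * (ib - ia))
  idx <- (ia + k):(ib - k)
  idx <- idx[!is.na(length_mm[idx])]
  if (length(idx) < 3) return(fallback)
  stats::coef(stats::lm.fit(cbind(1, time[idx]),
                            length_mm[idx]))[2]
}

# contiguous runs of TRUE
valid_segments <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Alternating extrema of the body-length signal
#'
#' Finds local minima and maxima of the lightly smoothed body-length
#' signal with topographic prominence at least \code{min_prominence},
#' then enforces strict min/max alternation (of consecutive same-type
#' extrema the more extreme one is kept). Invalid frames split the signal;
#' extrema are never detected across a gap. Reported values are read from
#' the raw (unsmoothed) signal at the detected positions.
#'
#' @param length_mm Per-frame body length, mm (NA = gap).
#' @param time Frame times, s.
#' @param min_prominence Minimum prominence, mm.
#' @param frame_rate Frames per second.
#' @param smooth_window Moving-average window, s (0 disables smoothing).
#' @return Data frame with columns \code{type} ("min"/"max"),
#'   \code{index}, \code{time}, \code{value} (raw length at the
#'   extremum) and \code{segment} (contiguous valid block id).
#' @export
length_extrema <- function(length_mm, time, min_prominence,
                           frame_rate, smooth_window = 0.4) {
  ok <- !is.na(length_mm)
  if (!any(ok))
    return(data.frame(type = character(0), index = integer(0),
                      time = numeric(0), value = numeric(0),
                      segment = integer(0)))
  segs <- valid_segments(ok)
  w <- max(1, round(smooth_window * frame_rate))
  out <- list()
  for (sgi in seq_len(nrow(segs))) {
    i0 <- segs$start[sgi]; i1 <- segs$end[sgi]
    if (i1 - i0 < 2) next
    raw <- length_mm[i0:i1]
    s <- moving_average(raw, w)
    ext <- local_extrema_idx(s)
    pk_max <- ext$max[peak_prominence(s, ext$max) >= min_prominence]
    pk_min <- ext$min[peak_prominence(-s, ext$min) >= min_prominence]
    if (!length(pk_max) && !length(pk_min)) next
    cand <- rbind(
      if (length(pk_max)) data.frame(type = "max", local = pk_max),
      if (length(pk_min)) data.frame(type = "min", local = pk_min))
    cand <- cand[order(cand$local), , drop = FALSE]
    cand$sval <- s[cand$local]
    # enforce alternation
    keep <- rep(TRUE, nrow(cand))
    last <- 1
    if (nrow(cand) > 1) {
      for (k in 2:nrow(cand)) {
        if (cand$type[k] == cand$type[last]) {
          better <- if (cand$type[k] == "max") cand$sval[k] > cand$sval[last]
                    else cand$sval[k] < cand$sval[last]
          if (better) { keep[last] <- FALSE; last <- k }
          else keep[k] <- FALSE
        } else last <- k
      }
    }
    cand <- cand[keep, , drop = FALSE]
    gidx <- cand$local + i0 - 1
    out[[length(out) + 1]] <- data.frame(
      type = cand$type, index = gidx, time = time[gidx],
      value = length_mm[gidx], segment = sgi)
  }
  if (!length(out))
    return(data.frame(type = character(0), index = integer(0),
                      time = numeric(0), value = numeric(0),
                      segment = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify frames as striding vs non-striding
#'
#' A minimum-to-minimum interval of the body-length signal is an accepted
#' stride when (i) its duration lies within the period bounds, (ii) its
#' length excursion is at least the prominence threshold, and (iii) the
#' body center advances at least \code{min_stride_displacement} over the
#' interval — rhythmic length change without travel (e.g. bending in
#' place) is not striding. Frames inside accepted strides are striding.
#'
#' @param series A [pose_series()].
#' @param extrema Output of [length_extrema()].
#' @param config A [run_config()].
#' @param length_mm Optional precomputed per-frame body length.
#' @return List with \code{striding} (per-frame logical), and
#'   \code{intervals}: one row per accepted stride (frame and time bounds,
#'   interior maximum).
#' @export
classify_striding <- function(series, extrema, config = run_config(),
                              length_mm = NULL) {
  n <- nrow(series)
  striding <- rep(FALSE, n)
  if (is.null(length_mm)) length_mm <- body_length(series)
  cen <- point_xy(series, 7)
  mins <- which(extrema$type == "min")
  iv <- list()
  if (length(mins) >= 2) {
    for (k in seq_len(length(mins) - 1)) {
      a <- mins[k]; b <- mins[k + 1]
      if (extrema$segment[a] != extrema$segment[b]) next
      between <- extrema[(a + 1):(b - 1), , drop = FALSE]
      maxs <- between[between$type == "max", , drop = FALSE]
      if (nrow(maxs) != 1) next  # interval lacking its interior maximum
      i1 <- extrema$index[a]; i2 <- extrema$index[b]
      dur <- series$time[i2] - series$time[i1]
      if (dur < config$period_min || dur > config$period_max) next
      exc <- maxs$value - min(extrema$value[a], extrema$value[b])
      min_prom <- config$min_prominence_frac *
        mean(length_mm, na.rm = TRUE)
      if (is.na(exc) || exc < min_prom) next
      disp <- sqrt(sum((cen[i2, ] - cen[i1, ])^2))
      if (is.na(disp) || disp < config$min_stride_displacement) next
      iv[[length(iv) + 1]] <- data.frame(
        i_start = i1, i_max = maxs$index, i_end = i2,
        t_start = series$time[i1], t_max = maxs$time,
        t_end = series$time[i2])
    }
  }
  intervals <- if (length(iv)) do.call(rbind, iv) else
    data.frame(i_start = integer(0), i_max = integer(0),
               i_end = integer(0), t_start = numeric(0),
               t_max = numeric(0), t_end = numeric(0))
  for (k in seq_len(nrow(intervals)))
    striding[intervals$i_start[k]:(intervals$i_end[k] - 1)] <- TRUE
  list(striding = striding, intervals = intervals)
}

#' Segment accepted stride intervals into stride events
#'
#' One event per accepted minimum-to-minimum interval: timing, center-point
#' displacement, the length extrema, and the contraction and extension
#' rates — the rate of body-length change during each phase of the stride,
#' estimated as the slope of a linear fit over the interior of the phase
#' (equivalent to the length change divided by the phase duration for a
#' linear phase, but robust to frame-resolution jitter in the extremum
#' positions).
#'
#' @param series A [pose_series()].
#' @param intervals Accepted intervals from [classify_striding()].
#' @param length_mm Optional precomputed per-frame body length.
#' @return Data frame of class \code{stride_events}: \code{t_start},
#'   \code{t_end}, \code{duration}, \code{distance}, \code{length_min},
#'   \code{length_max}, \code{contraction_rate}, \code{extension_rate}.
#' @export
segment_strides <- function(series, intervals, length_mm = NULL) {
  if (is.null(length_mm)) length_mm <- body_length(series)
  cen <- point_xy(series, 7)
  n <- nrow(intervals)
  out <- data.frame(t_start = numeric(n), t_end = numeric(n),
                    duration = numeric(n), distance = numeric(n),
                    length_min = numeric(n), length_max = numeric(n),
                    contraction_rate = numeric(n),
                    extension_rate = numeric(n))
  for (k in seq_len(n)) {
    i1 <- intervals$i_start[k]; im <- intervals$i_max[k]
    i2 <- intervals$i_end[k]
    t1 <- intervals$t_start[k]; tm <- intervals$t_max[k]
    t2 <- intervals$t_end[k]
    L1 <- length_mm[i1]; Lm <- length_mm[im]; L2 <- length_mm[i2]
    out$t_start[k] <- t1; out$t_end[k] <- t2
    out$duration[k] <- t2 - t1
    out$distance[k] <- sqrt(sum((cen[i2, ] - cen[i1, ])^2))
    out$length_min[k] <- min(L1, L2)
    out$length_max[k] <- Lm
    out$extension_rate[k] <- phase_rate(length_mm, series$time, i1, im,
                                        (Lm - L1) / (tm - t1))
    out$contraction_rate[k] <- phase_rate(length_mm, series$time, im, i2,
                                          (L2 - Lm) / (t2 - tm))
  }
  out$contraction_rate <- abs(out$contraction_rate)
  out$extension_rate <- abs(out$extension_rate)
  class(out) <- c("stride_events", "data.frame")
  out
}

#' Group strides into runs
#'
#' A run is a maximal period of continuous striding: consecutive strides
#' whose boundary gap is at most \code{max_gap} belong to the same run.
#' Run distance is the path distance of the (smoothed) body center over
#' the run.
#'
#' @param series A [pose_series()].
#' @param strides A \code{stride_events} data frame.
#' @param config A [run_config()] (uses \code{max_gap},
#'   \code{track_smooth}).
#' @return Data frame of class \code{run_events}: \code{t_start},
#'   \code{t_end}, \code{duration}, \code{distance}, \code{stride_count}.
#' @export
detect_runs <- function(series, strides, config = run_config()) {
  if (nrow(strides) == 0)
    return(structure(data.frame(t_start = numeric(0), t_end = numeric(0),
                                duration = numeric(0),
                                distance = numeric(0),
                                stride_count = integer(0)),
                     class = c("run_events", "data.frame")))
  o <- order(strides$t_start)
  st <- strides[o, , drop = FALSE]
  gap <- c(Inf, st$t_start[-1] - st$t_end[-nrow(st)])
  run_id <- cumsum(gap > config$max_gap)
  fr <- frame_rate_of(series)
  cen <- point_xy(series, 7)
  w <- max(1, round(config$track_smooth * fr))
  xs <- moving_average(cen[, 1], w)
  ys <- moving_average(cen[, 2], w)
  out <- lapply(split(seq_len(nrow(st)), run_id), function(ix) {
    t0 <- min(st$t_start[ix]); t1 <- max(st$t_end[ix])
    fidx <- which(series$time >= t0 - 1e-9 & series$time <= t1 + 1e-9 &
                  series$valid)
    d <- if (length(fidx) >= 2)
      sum(sqrt(diff(xs[fidx])^2 + diff(ys[fidx])^2)) else 0
    data.frame(t_start = t0, t_end = t1, duration = t1 - t0,
               distance = d, stride_count = length(ix))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("run_events", "data.frame")
  res
}

#' Full stride analysis of a pose series
#'
#' Runs [length_extrema()], [classify_striding()], [segment_strides()]
#' and [detect_runs()] with the thresholds in \code{config}.
#'
#' @param series A [pose_series()].
#' @param config A [run_config()].
#' @return List with \code{length_mm}, \code{extrema}, \code{striding}
#'   (per-frame logical), \code{strides}, \code{runs}.
#' @export
stride_analysis <- function(series, config = run_config()) {
  len <- body_length(series)
  fr <- frame_rate_of(series)
  min_prom <- config$min_prominence_frac * mean(len, na.rm = TRUE)
  ext <- length_extrema(len, series$time, min_prom, fr,
                        config$smooth_length)
  cls <- classify_striding(series, ext, config, len)
  strides <- segment_strides(series, cls$intervals, len)
  runs <- detect_runs(series, strides, config)
  list(length_mm = len, extrema = ext, striding = cls$striding,
       strides = strides, runs = runs)
}
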