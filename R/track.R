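# Track-level measures: total path distance, direction-change points and
# the inside/outside-ring partition of the session.

#' Arena geometry
#'
#' Describes the circular assay plate and the confinement ring on its outer
#' rim (default: 10 cm dish, 1.5 cm ring, centered at the plate origin).
#'
#' @param plate_center Numeric length-2, plate center in mm.
#' @param plate_radius Plate radius, mm.
#' @param ring_width Ring width, mm; the inner edge of the ring lies at
#'   \code{plate_radius - ring_width} from the center.
#' @return An object of class \code{arena_geometry}.
#' @export
arena_geometry <- function(plate_center = c(0, 0), plate_radius = 50,
                           ring_width = 15) {
  stopifnot(length(plate_center) == 2, ring_width > 0,
            ring_width < plate_radius)
  structure(list(plate_center = as.numeric(plate_center),
                 plate_radius = plate_radius, ring_width = ring_width),
            class = "arena_geometry")
}

# centered moving average tolerating NA gaps; window in frames (odd).
# Edge windows are truncated rather than dropped, so the first and last
# frames are still denoised by their available neighbors.
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n < 3) return(x)
  w <- min(w, n)
  if (w %% 2 == 0) w <- w - 1
  if (w <= 1) return(x)
  h <- (w - 1) / 2
  # odd (point) reflection padding: linear trends pass through unchanged,
  # so smoothing never clips the ends of a straight track
  left <- if (is.na(x[1])) rep(NA_real_, h) else
    2 * x[1] - x[pmin(n, 1 + (h:1))]
  right <- if (is.na(x[n])) rep(NA_real_, h) else
    2 * x[n] - x[pmax(1, n - (1:h))]
  xp <- c(left, x, right)
  okp <- !is.na(xp)
  csum <- cumsum(c(0, ifelse(okp, xp, 0)))
  ccnt <- cumsum(c(0, as.numeric(okp)))
  i <- seq_len(n)
  num <- csum[i + 2 * h + 1] - csum[i]
  den <- ccnt[i + 2 * h + 1] - ccnt[i]
  out <- ifelse(den > 0, num / den, NA_real_)
  out[is.na(x)] <- NA_real_
  out
}

#' Total distance traveled by the body center
#'
#' Sums consecutive displacements of the (lightly smoothed) center-point
#' track over valid frames, and normalizes by the tracked duration to
#' mm/min. Smoothing suppresses the pixel-jitter inflation that a raw sum
#' of per-frame displacements suffers.
#'
#' @param xy n x 2 matrix of center positions, mm (NA rows = invalid).
#' @param time Frame times, s.
#' @param smooth_window Smoothing window, s (0 disables smoothing).
#' @param frame_rate Frames per second (used to size the window).
#' @return List with \code{mm} (total path length), \code{mm_per_min}, and
#'   the smoothed track.
#' @export
path_distance <- function(xy, time, smooth_window = 0.5, frame_rate = NULL) {
  ok <- complete.cases(xy)
  if (sum(ok) < 2) return(list(mm = NA_real_, mm_per_min = NA_real_,
                               smoothed = xy))
  if (is.null(frame_rate)) {
    dt <- diff(time)
    frame_rate <- 1 / median(dt[dt > 0])
  }
  w <- max(1, round(smooth_window * frame_rate))
  xs <- moving_average(xy[, 1], w)
  ys <- moving_average(xy[, 2], w)
  x2 <- xs[ok]; y2 <- ys[ok]; t2 <- time[ok]
  d <- sum(sqrt(diff(x2)^2 + diff(y2)^2))
  span <- t2[length(t2)] - t2[1]
  list(mm = d, mm_per_min = if (span > 0) d / span * 60 else NA_real_,
       smoothed = cbind(xs, ys))
}

#' Direction-change points along a track
#'
#' The track is subsampled at a fixed interval; at each interior sample the
#' turning angle between the incoming and outgoing displacement vectors is
#' computed, and samples turning more than the threshold are marked as
#' direction changes. The reported fraction is changes / interior samples.
#'
#' @param xy n x 2 matrix of center positions, mm.
#' @param time Frame times, s.
#' @param sample_interval Subsampling interval, s.
#' @param turn_threshold Turning angle threshold, degrees.
#' @return List with \code{fraction}, a data frame \code{points}
#'   (time, x, y, angle, change) of interior samples, and \code{n_samples}.
#' @export
direction_changes <- function(xy, time, sample_interval = 1,
                              turn_threshold = 60) {
  ok <- complete.cases(xy)
  if (sum(ok) < 3) return(list(fraction = NA_real_,
                               points = NULL, n_samples = 0L))
  t2 <- time[ok]
  x2 <- xy[ok, 1]; y2 <- xy[ok, 2]
  st <- seq(t2[1], t2[length(t2)], by = sample_interval)
  if (length(st) < 3) return(list(fraction = NA_real_,
                                  points = NULL, n_samples = 0L))
  ix <- vapply(st, function(s) which.min(abs(t2 - s)), integer(1))
  ix <- ix[!duplicated(ix)]
  if (length(ix) < 3) return(list(fraction = NA_real_,
                                  points = NULL, n_samples = 0L))
  sx <- x2[ix]; sy <- y2[ix]
  vx <- diff(sx); vy <- diff(sy)
  seg_len <- sqrt(vx^2 + vy^2)
  m <- length(ix) - 2  # interior samples
  ang <- rep(NA_real_, m)
  for (k in seq_len(m)) {
    if (seg_len[k] < 1e-9 || seg_len[k + 1] < 1e-9) next  # degenerate
    dot <- vx[k] * vx[k + 1] + vy[k] * vy[k + 1]
    crs <- vx[k] * vy[k + 1] - vy[k] * vx[k + 1]
    ang[k] <- atan2(abs(crs), dot) * 180 / pi
  }
  change <- !is.na(ang) & ang > turn_threshold
  usable <- !is.na(ang)
  frac <- if (any(usable)) sum(change) / sum(usable) else NA_real_
  pts <- data.frame(time = t2[ix][2:(length(ix) - 1)],
                    x = sx[2:(length(ix) - 1)], y = sy[2:(length(ix) - 1)],
                    angle = ang, change = change)
  list(fraction = frac, points = pts, n_samples = sum(usable))
}

#' Inside/outside-ring partition
#'
#' A frame counts as "inside" when the body center is farther than
#' \code{inside_margin} from the inner edge of the confinement ring, i.e.,
#' at radial distance below
#' \code{plate_radius - ring_width - inside_margin}. Frames beyond the
#' plate radius are flagged suspicious and counted outside.
#'
#' @param xy n x 2 matrix of center positions, mm.
#' @param arena An [arena_geometry()].
#' @param inside_margin Margin from the ring's inner edge, mm (convention:
#'   half a body length — an animal within half a body length of the
#'   plastic counts as "close to" it).
#' @return List with logical \code{inside}, \code{fraction} (over valid
#'   frames), and logical \code{suspicious}.
#' @export
inside_mask <- function(xy, arena, inside_margin) {
  stopifnot(inherits(arena, "arena_geometry"))
  r <- sqrt((xy[, 1] - arena$plate_center[1])^2 +
            (xy[, 2] - arena$plate_center[2])^2)
  boundary <- arena$plate_radius - arena$ring_width - inside_margin
  inside <- r < boundary
  suspicious <- !is.na(r) & r > arena$plate_radius
  inside[suspicious] <- FALSE
  ok <- !is.na(inside)
  list(inside = inside,
       fraction = if (any(ok)) mean(inside[ok]) else NA_real_,
       suspicious = suspicious, boundary_radius = boundary)
}

#' Track-level analysis of a pose series
#'
#' Convenience wrapper running [path_distance()], [direction_changes()] and
#' [inside_mask()] on the center point (point 7) of a pose series.
#'
#' @param series A [pose_series()].
#' @param config A [run_config()].
#' @param arena An [arena_geometry()]; defaults to the plate described in
#'   \code{config}.
#' @return List with components \code{distance}, \code{changes},
#'   \code{inside}.
#' @export
track_analysis <- function(series, config = run_config(), arena = NULL) {
  if (is.null(arena))
    arena <- arena_geometry(plate_radius = config$plate_radius,
                            ring_width = config$ring_width)
  cen <- point_xy(series, 7)
  fr <- frame_rate_of(series)
  margin <- config$inside_margin
  if (is.na(margin)) {
    bl <- body_length(series)
    margin <- if (all(is.na(bl))) 0 else mean(bl, na.rm = TRUE) / 2
  }
  list(distance = path_distance(cen, series$time, config$track_smooth, fr),
       changes = direction_changes(cen, series$time,
                                   config$sample_interval,
                                   config$turn_threshold),
       inside = inside_mask(cen, arena, margin))
}
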