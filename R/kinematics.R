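# Per-frame shape and motion measures: body length, per-point speed,
# head/body bend angles and the 45-degree bending flags.

#' Body length of a pose
#'
#' Sum of the 12 inter-point Euclidean distances along the midline.
#'
#' @param x A 13 x 2 pose matrix or a [pose_series()].
#' @return A single length (mm) for a pose matrix, or a per-frame vector
#'   (NA for invalid frames) for a series.
#' @export
body_length <- function(x) UseMethod("body_length")

#' @export
body_length.matrix <- function(x) {
  sum(sqrt(rowSums(diff(x)^2)))
}

#' @export
body_length.pose_series <- function(x) {
  P <- pose_points(x)
  out <- rep(NA_real_, nrow(P))
  for (k in 1:12) {
    dx <- P[, 2 * k + 1] - P[, 2 * k - 1]
    dy <- P[, 2 * k + 2] - P[, 2 * k]
    seg <- sqrt(dx^2 + dy^2)
    out <- if (k == 1) seg else out + seg
  }
  out
}

#' Instantaneous speed of one midline point
#'
#' Central-difference displacement of the point over a time window divided
#' by the elapsed time. The window (default 0.5 s, about 4 frames at
#' 7.5 fps) is shorter than one stride, preserving the within-stride
#' head/tail speed alternation while suppressing pixel jitter. Gaps
#' (invalid frames at either end of the window) propagate as NA.
#'
#' @param series A [pose_series()].
#' @param point Midline point index, 1 (head) to 13 (tail); default the
#'   center point 7.
#' @param window Window length, s; must cover at least 2 frames.
#' @return Per-frame speeds, mm/s.
#' @export
point_speed <- function(series, point = 7, window = 0.5) {
  fr <- frame_rate_of(series)
  k <- round(window * fr / 2)
  if (2 * k < 1) stop("speed window must span at least 2 frames",
                      call. = FALSE)
  k <- max(1, k)
  xy <- point_xy(series, point)
  n <- nrow(xy)
  out <- rep(NA_real_, n)
  lo <- seq_len(n) - k
  hi <- seq_len(n) + k
  ok <- lo >= 1 & hi <= n
  il <- lo[ok]; ih <- hi[ok]
  d <- sqrt((xy[ih, 1] - xy[il, 1])^2 + (xy[ih, 2] - xy[il, 2])^2)
  dt <- series$time[ih] - series$time[il]
  out[ok] <- d / dt
  out
}

angle_between_deg <- function(v1, v2) {
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  out <- rep(NA_real_, nrow(v1))
  ok <- !is.na(n1) & !is.na(n2) & n1 > 1e-9 & n2 > 1e-9
  dot <- rowSums(v1 * v2)
  crs <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  out[ok] <- atan2(abs(crs[ok]), dot[ok]) * 180 / pi
  out
}

#' Head and body bend angles
#'
#' \code{head_angle} is the angle between the head chord (point 3 to point
#' 1) and the anterior body chord (point 7 to point 3); \code{body_angle}
#' is the deviation from straight of the bend at the center: 180 degrees
#' minus the interior angle at point 7 between the chords to point 1 and
#' point 13. Both are unsigned, in \code{[0, 180]}; a perfectly straight
#' pose scores 0 on both.
#'
#' @param x A 13 x 2 pose matrix or a [pose_series()].
#' @return Angle(s) in degrees; NA where a chord has zero length or the
#'   frame is invalid.
#' @export
head_angle <- function(x) UseMethod("head_angle")

#' @export
head_angle.matrix <- function(x) {
  angle_between_deg(matrix(x[1, ] - x[3, ], 1),
                    matrix(x[3, ] - x[7, ], 1))
}

#' @export
head_angle.pose_series <- function(x) {
  P <- pose_points(x)
  v1 <- cbind(P[, 1] - P[, 5], P[, 2] - P[, 6])     # p1 - p3
  v2 <- cbind(P[, 5] - P[, 13], P[, 6] - P[, 14])   # p3 - p7
  angle_between_deg(v1, v2)
}

#' @rdname head_angle
#' @export
body_angle <- function(x) UseMethod("body_angle")

#' @export
body_angle.matrix <- function(x) {
  180 - angle_between_deg(matrix(x[1, ] - x[7, ], 1),
                          matrix(x[13, ] - x[7, ], 1))
}

#' @export
body_angle.pose_series <- function(x) {
  P <- pose_points(x)
  v1 <- cbind(P[, 1] - P[, 13], P[, 2] - P[, 14])   # p1 - p7
  v2 <- cbind(P[, 25] - P[, 13], P[, 26] - P[, 14]) # p13 - p7
  180 - angle_between_deg(v1, v2)
}

#' Bending flags from bend angles
#'
#' A frame is head-bending (resp. body-bending) when the head (resp. body)
#' angle is strictly over the threshold, 45 degrees by convention;
#' \code{bending} is the logical OR of the two.
#'
#' @param head_angle,body_angle Angles in degrees.
#' @param threshold Threshold, degrees.
#' @return Data frame with logical columns \code{head_bending},
#'   \code{body_bending}, \code{bending}.
#' @export
bending_flags <- function(head_angle, body_angle, threshold = 45) {
  hb <- !is.na(head_angle) & head_angle > threshold
  bb <- !is.na(body_angle) & body_angle > threshold
  data.frame(head_bending = hb, body_bending = bb, bending = hb | bb)
}

#' Per-frame metrics table
#'
#' Computes, for every frame: body length, the speed of each of the 13
#' midline points, head and body angles and the bending flags. The
#' \code{striding} and \code{inside} columns are filled by
#' [stride_analysis()] / [track_analysis()] via [summarize_video()].
#'
#' @param series A [pose_series()].
#' @param config A [run_config()].
#' @return A data frame with one row per frame: \code{time}, \code{valid},
#'   \code{length}, \code{speed_p1} ... \code{speed_p13}, \code{speed}
#'   (center point), \code{head_angle}, \code{body_angle},
#'   \code{head_bending}, \code{body_bending}, \code{bending}.
#' @export
frame_metrics <- function(series, config = run_config()) {
  stopifnot(inherits(series, "pose_series"))
  sp <- sapply(1:13, function(k)
    point_speed(series, k, config$speed_window))
  colnames(sp) <- paste0("speed_p", 1:13)
  ha <- head_angle(series)
  ba <- body_angle(series)
  fl <- bending_flags(ha, ba, config$bend_threshold)
  df <- data.frame(time = series$time, valid = series$valid,
                   length = body_length(series), sp,
                   speed = sp[, 7], head_angle = ha, body_angle = ba,
                   fl, striding = NA, inside = NA)
  df
}
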