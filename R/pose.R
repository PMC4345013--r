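pose_cols <- function() {
  as.vector(t(outer(1:13, c("x", "y"), function(i, a) paste0(a, i))))
}

#' Construct a pose series
#'
#' A pose series is the central data structure of the pipeline: one row per
#' video frame, holding the 13 ordered midline points in plate coordinates
#' (mm, head = point 1, center = point 7, tail = point 13), a validity flag
#' and a frame timestamp. Invalid frames carry \code{NA} point data and a
#' reason code.
#'
#' @param frame Integer frame indices (1-based).
#' @param time Frame times, s.
#' @param points Numeric matrix with \code{length(frame)} rows and 26
#'   columns (x1, y1, ..., x13, y13), or \code{NULL} for an all-invalid
#'   series.
#' @param valid Logical per-frame validity.
#' @param reason Character per-frame failure reason ("" when valid).
#' @param frame_rate Frames per second (stored as an attribute).
#' @return A data frame of class \code{pose_series}.
#' @export
pose_series <- function(frame, time, points = NULL,
                        valid = rep(TRUE, length(frame)),
                        reason = rep("", length(frame)),
                        frame_rate) {
  n <- length(frame)
  if (is.null(points)) points <- matrix(NA_real_, n, 26)
  stopifnot(nrow(points) == n, ncol(points) == 26, length(time) == n)
  points[!valid, ] <- NA_real_
  df <- data.frame(frame = as.integer(frame), time = time,
                   valid = as.logical(valid), reason = reason,
                   points)
  names(df)[5:30] <- pose_cols()
  attr(df, "frame_rate") <- frame_rate
  class(df) <- c("pose_series", "data.frame")
  df
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> %d frames at %.3g fps, %d valid (%.1f%%)\n",
              nrow(x), attr(x, "frame_rate"), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

frame_rate_of <- function(series) {
  fr <- attr(series, "frame_rate")
  if (is.null(fr)) {
    dt <- diff(series$time)
    fr <- 1 / median(dt[dt > 0])
  }
  fr
}

#' Extract one frame's midline as a 13 x 2 matrix
#'
#' @param series A \code{pose_series}.
#' @param i Row index.
#' @return A 13 x 2 matrix (columns x, y) or \code{NULL} for invalid frames.
#' @export
pose_matrix <- function(series, i) {
  if (!series$valid[i]) return(NULL)
  v <- as.numeric(series[i, 5:30])
  matrix(v, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

#' Per-frame coordinates of one midline point
#'
#' @param series A \code{pose_series}.
#' @param point Point index 1 (head) to 13 (tail); 7 is the body center.
#' @return An n x 2 matrix of (x, y) in mm; \code{NA} rows for invalid
#'   frames.
#' @export
point_xy <- function(series, point = 7) {
  stopifnot(point >= 1, point <= 13)
  cbind(x = series[[paste0("x", point)]], y = series[[paste0("y", point)]])
}

# points: n x 26 matrix view
pose_points <- function(series) {
  as.matrix(series[, pose_cols(), drop = FALSE])
}

# build one straight/bent pose: tail position, heading theta (rad), length L,
# head bend phi (rad) applied to the two head segments at point 3.
make_pose <- function(tail, theta, L, phi = 0) {
  seg <- L / 12
  u <- c(cos(theta), sin(theta))
  idx <- 13:3
  pts <- matrix(NA_real_, 13, 2)
  for (k in idx) {
    pts[k, ] <- tail + (13 - k) * seg * u
  }
  th2 <- theta + phi
  u2 <- c(cos(th2), sin(th2))
  pts[2, ] <- pts[3, ] + seg * u2
  pts[1, ] <- pts[3, ] + 2 * seg * u2
  pts
}

flatten_pose <- function(pts) as.vector(t(pts))
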