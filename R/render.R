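# Frame renderer: draws the worm as a dark capsule (stadium) around the
# midline on a white background, emulating the recorded video plus the
# tracker's stage-coordinate log. The stage re-centers whenever the worm
# centroid leaves the central third of the frame, and the per-frame stage
# position is logged so the recognizer can invert the mapping.
#
# The capsule is drawn over the midline trimmed by half the body width at
# each end, so the silhouette's total extent — and hence its medial axis
# after the recognizer's end extension — matches the true midline length.

# interpolate a polyline at arc-length positions s
interp_polyline <- function(pts, s) {
  d <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(d))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  cbind(approx(cum, pts[, 1], xout = s, ties = "ordered")$y,
        approx(cum, pts[, 2], xout = s, ties = "ordered")$y)
}

# pixel coordinates of plate-frame points given stage position; image
# origin top-left, pixel centers at integer coordinates, y down
plate_to_pixel <- function(pts_mm, stage, mm_per_pixel, frame_size) {
  cx <- (frame_size[1] + 1) / 2
  cy <- (frame_size[2] + 1) / 2
  cbind(cx + (pts_mm[, 1] - stage[1]) / mm_per_pixel,
        cy - (pts_mm[, 2] - stage[2]) / mm_per_pixel)
}

# render one pose (13 x 2 mm) into a [0,1] grayscale matrix (rows = y)
render_pose_frame <- function(pose_mm, stage, mm_per_pixel,
                              frame_size = c(240, 240), worm_width = 0.8) {
  w <- frame_size[1]; h <- frame_size[2]
  img <- matrix(1, nrow = h, ncol = w)
  pts <- plate_to_pixel(pose_mm, stage, mm_per_pixel, c(w, h))
  r_px <- (worm_width / 2) / mm_per_pixel
  # trim midline by the capsule radius at each end
  d <- sqrt(rowSums(diff(pts)^2))
  total <- sum(d)
  trim <- min(r_px, total / 4)
  s <- seq(trim, total - trim, length.out = 15)
  poly <- interp_polyline(pts, s)
  xmin <- max(1, floor(min(poly[, 1]) - r_px - 2))
  xmax <- min(w, ceiling(max(poly[, 1]) + r_px + 2))
  ymin <- max(1, floor(min(poly[, 2]) - r_px - 2))
  ymax <- min(h, ceiling(max(poly[, 2]) + r_px + 2))
  if (xmin > xmax || ymin > ymax) return(img)
  gx <- xmin:xmax; gy <- ymin:ymax
  PX <- rep(gx, each = length(gy))
  PY <- rep(gy, times = length(gx))
  dmin <- rep(Inf, length(PX))
  for (k in seq_len(nrow(poly) - 1)) {
    ax <- poly[k, 1]; ay <- poly[k, 2]
    bx <- poly[k + 1, 1]; by <- poly[k + 1, 2]
    wx <- bx - ax; wy <- by - ay
    len2 <- wx * wx + wy * wy
    if (len2 < 1e-12) {
      dd <- sqrt((PX - ax)^2 + (PY - ay)^2)
    } else {
      tt <- ((PX - ax) * wx + (PY - ay) * wy) / len2
      tt[tt < 0] <- 0; tt[tt > 1] <- 1
      dd <- sqrt((PX - ax - tt * wx)^2 + (PY - ay - tt * wy)^2)
    }
    dmin <- pmin(dmin, dd)
  }
  inside <- dmin <= r_px
  if (any(inside)) {
    rows <- PY[inside]; cols <- PX[inside]
    img[cbind(rows, cols)] <- 0
  }
  img
}

#' Render a pose series to video frames with an emulated centering stage
#'
#' Draws each frame as a dark worm (a capsule around the midline) on a
#' white background, moving a virtual stage to keep the worm centroid
#' within the central third of the frame, exactly as a motorized-stage
#' tracker does. Returns (or writes) the frames together with the stage
#' log needed to reconstruct plate coordinates.
#'
#' @param series A [pose_series()] in plate-frame mm.
#' @param mm_per_pixel Calibration, mm per pixel.
#' @param frame_size Frame size in pixels, \code{c(width, height)}.
#' @param worm_width Body width, mm; must exceed 2 pixels at the given
#'   calibration.
#' @param output_dir If non-NULL, frames are written as numbered 8-bit
#'   grayscale PNGs (\code{frame_000001.png}, ...) and the stage log as
#'   \code{stage_log.tsv} in this directory; otherwise frames are returned
#'   in memory.
#' @param recenter_frac The stage re-centers when the centroid drifts more
#'   than this fraction of the frame from the center (1/3 = central third).
#' @return List with \code{stage_log} (frame_index, time_s, stage_x_mm,
#'   stage_y_mm), \code{mm_per_pixel}, \code{frame_size}, and either
#'   \code{frames} (list of matrices) or \code{dir} and \code{files}.
#' @export
render_frames <- function(series, mm_per_pixel = 0.05,
                          frame_size = c(240, 240), worm_width = 0.8,
                          output_dir = NULL, recenter_frac = 1 / 3) {
  stopifnot(inherits(series, "pose_series"))
  if (length(frame_size) == 1) frame_size <- rep(frame_size, 2)
  if (worm_width / mm_per_pixel <= 2)
    stop("calibration error: worm width ", worm_width,
         " mm is <= 2 pixels at ", mm_per_pixel, " mm/pixel", call. = FALSE)
  n <- nrow(series)
  to_disk <- !is.null(output_dir)
  if (to_disk && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  frames <- if (to_disk) NULL else vector("list", n)
  files <- character(n)
  stage <- matrix(NA_real_, n, 2)
  S <- NULL
  half_band <- frame_size * recenter_frac / 2  # px from center, per axis
  for (i in seq_len(n)) {
    pm <- pose_matrix(series, i)
    if (is.null(pm)) {
      # invalid pose: blank frame, stage holds
      if (is.null(S)) S <- c(0, 0)
      img <- matrix(1, nrow = frame_size[2], ncol = frame_size[1])
    } else {
      centroid <- colMeans(pm)
      if (is.null(S)) S <- centroid
      off_px <- abs(centroid - S) / mm_per_pixel
      if (off_px[1] > half_band[1] || off_px[2] > half_band[2]) S <- centroid
      img <- render_pose_frame(pm, S, mm_per_pixel, frame_size, worm_width)
    }
    stage[i, ] <- S
    if (to_disk) {
      fn <- file.path(output_dir, sprintf("frame_%06d.png", series$frame[i]))
      png::writePNG(img, fn)
      files[i] <- fn
    } else {
      frames[[i]] <- img
    }
  }
  log <- data.frame(frame_index = series$frame, time_s = series$time,
                    stage_x_mm = stage[, 1], stage_y_mm = stage[, 2])
  if (to_disk) {
    write_stage_log(log, file.path(output_dir, "stage_log.tsv"))
    list(stage_log = log, dir = output_dir, files = files,
         mm_per_pixel = mm_per_pixel, frame_size = frame_size)
  } else {
    list(stage_log = log, frames = frames, mm_per_pixel = mm_per_pixel,
         frame_size = frame_size)
  }
}

#' Read / write a stage-coordinate log
#'
#' Tab-separated text with columns \code{frame_index}, \code{time_s},
#' \code{stage_x_mm}, \code{stage_y_mm} — the record of how the motorized
#' stage moved to keep the animal centered.
#'
#' @param log Data frame with the four columns above.
#' @param path File path.
#' @return \code{read_stage_log} returns the data frame.
#' @export
write_stage_log <- function(log, path) {
  stopifnot(all(c("frame_index", "time_s", "stage_x_mm", "stage_y_mm")
                %in% names(log)))
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_log
#' @export
read_stage_log <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("frame_index", "time_s", "stage_x_mm", "stage_y_mm")
  if (!all(need %in% names(df)))
    stop("stage log ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}
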