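# Recognizer: frames + stage log -> plate-frame 13-point midline per frame.
# Pipeline per frame: binarize (Otsu), keep the largest component, fill
# holes, thin to a skeleton, prune spurious branches, order the pixels
# endpoint to endpoint, extend the ends to the silhouette boundary, smooth,
# and resample at 12 equal arc-length intervals. Stage coordinates then map
# pixel points to plate millimetres, and a speed heuristic orients head vs
# tail over the whole series.

#' Calibration between image pixels and plate millimetres
#'
#' @param mm_per_pixel Millimetres per pixel (> 0).
#' @param axis_orientation One of \code{"+x+y"}, \code{"+x-y"},
#'   \code{"-x+y"}, \code{"-x-y"}: the signs applied to the pixel offsets
#'   (x right, y down from the image center) to obtain plate offsets
#'   (x right, y up). The default \code{"+x-y"} flips the image y axis.
#' @return An object of class \code{calibration_info}.
#' @export
calibration_info <- function(mm_per_pixel, axis_orientation = "+x-y") {
  stopifnot(mm_per_pixel > 0)
  if (!axis_orientation %in% c("+x+y", "+x-y", "-x+y", "-x-y"))
    stop("axis_orientation must be one of +x+y, +x-y, -x+y, -x-y",
         call. = FALSE)
  structure(list(mm_per_pixel = mm_per_pixel,
                 axis_orientation = axis_orientation),
            class = "calibration_info")
}

#' Binarize one grayscale frame
#'
#' Thresholds a high-contrast frame (dark animal on light background),
#' keeps the largest connected foreground component, fills interior holes,
#' and checks the component area against plausible animal-size bounds.
#'
#' @param img Numeric matrix in \code{[0, 1]} (rows = image y).
#' @param config A [run_config()]; uses \code{threshold} (NA = Otsu),
#'   \code{min_area}, \code{max_area} (mm^2) and \code{mm_per_pixel}.
#' @return List with \code{mask} (logical matrix), \code{valid},
#'   \code{reason} and \code{area_mm2}.
#' @export
binarize_frame <- function(img, config = run_config()) {
  stopifnot(is.matrix(img))
  if (max(img) > 1) img <- img / 255
  thr <- config$threshold
  if (is.na(thr)) {
    rng <- range(img)
    if (diff(rng) < 0.05) {
      return(list(mask = NULL, valid = FALSE, reason = "no_component",
                  area_mm2 = 0))
    }
    thr <- EBImage::otsu(EBImage::Image(img), range = rng)
  }
  fg <- img < thr
  if (!any(fg))
    return(list(mask = NULL, valid = FALSE, reason = "no_component",
                area_mm2 = 0))
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  lab <- EBImage::imageData(lab)
  tab <- tabulate(lab[lab > 0])
  px_area <- config$mm_per_pixel^2
  keep <- which.max(tab)
  mask <- lab == keep
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
  area <- sum(mask) * px_area
  if (area < config$min_area || area > config$max_area)
    return(list(mask = NULL, valid = FALSE, reason = "area",
                area_mm2 = area))
  list(mask = mask, valid = TRUE, reason = "", area_mm2 = area)
}

# 8-neighbor counts for every pixel of a logical matrix
neighbor_counts <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    cnt <- cnt + p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  cnt
}

# walk from a start pixel until hitting a junction (>=3 neighbors) or a
# dead end; pixels as (row, col). Used both for branch measurement and for
# final path ordering.
walk_path <- function(skel, start, stop_at_junction = TRUE) {
  nr <- nrow(skel)
  visited <- matrix(FALSE, nr, ncol(skel))
  cnt <- neighbor_counts(skel)
  path <- matrix(0L, sum(skel), 2)
  cur <- start
  np <- 0L
  repeat {
    np <- np + 1L
    path[np, ] <- cur
    visited[cur[1], cur[2]] <- TRUE
    if (stop_at_junction && np > 1 && cnt[cur[1], cur[2]] >= 3) break
    # unvisited neighbors, 4-connected first
    cand <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
      i <- cur[1] + d[1]; j <- cur[2] + d[2]
      if (i < 1 || j < 1 || i > nr || j > ncol(skel)) next
      if (skel[i, j] && !visited[i, j]) { cand <- c(i, j); break }
    }
    if (is.null(cand)) break
    cur <- cand
  }
  path[seq_len(np), , drop = FALSE]
}

#' Extract the ordered midline skeleton from a binary mask
#'
#' Computes the topological (Zhang-Suen) skeleton, prunes spurious side
#' branches shorter than \code{prune_frac} of the total skeleton length
#' until exactly two endpoints remain, orders the pixels by walking from
#' one endpoint to the other, and extends both ends along their local
#' tangents to the mask boundary (thinning erodes the skeleton ends by
#' about half the body width; the extension restores the full midline).
#'
#' @param mask Logical matrix, the cleaned single-component silhouette.
#' @param config A [run_config()].
#' @return List with \code{path} (n x 2 matrix of pixel coordinates,
#'   columns x, y, ordered endpoint to endpoint), \code{arc_length}
#'   (pixels), \code{ok} and \code{reason} (\code{"topology"} when the
#'   skeleton cannot be reduced to two endpoints).
#' @export
extract_skeleton <- function(mask, config = run_config()) {
  stopifnot(is.matrix(mask))
  fail <- function(reason) list(path = NULL, arc_length = NA_real_,
                                ok = FALSE, reason = reason)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- as.integer(mask)
  skel <- .thin_mask(pad)[2:(nr + 1), 2:(nc + 1)] > 0
  if (sum(skel) < 3) return(fail("topology"))
  # prune short branches until exactly two endpoints remain
  for (iter in seq_len(50)) {
    cnt <- neighbor_counts(skel)
    ends <- which(skel & cnt == 1, arr.ind = TRUE)
    if (nrow(ends) == 2) break
    if (nrow(ends) < 2) return(fail("topology"))  # loop or point
    total <- sum(skel)
    branches <- lapply(seq_len(nrow(ends)), function(k)
      walk_path(skel, ends[k, ], stop_at_junction = TRUE))
    lens <- vapply(branches, nrow, integer(1))
    shortest <- which.min(lens)
    if (lens[shortest] >= config$prune_frac * total)
      return(fail("topology"))
    br <- branches[[shortest]]
    # remove the branch but keep its junction pixel
    drop <- br[-nrow(br), , drop = FALSE]
    skel[drop] <- FALSE
  }
  cnt <- neighbor_counts(skel)
  ends <- which(skel & cnt == 1, arr.ind = TRUE)
  if (nrow(ends) != 2) return(fail("topology"))
  path_rc <- walk_path(skel, ends[1, ], stop_at_junction = FALSE)
  if (nrow(path_rc) < 0.8 * sum(skel)) return(fail("topology"))
  # (row, col) -> (x, y)
  path <- cbind(x = path_rc[, 2], y = path_rc[, 1])
  path <- extend_to_boundary(path, mask)
  # de-jag the 8-connected pixel chain: a small moving average removes the
  # diagonal staircase that otherwise inflates the arc length
  path <- smooth_path(path, config$path_smooth)
  d <- sqrt(rowSums(diff(path)^2))
  list(path = path, arc_length = sum(d), ok = TRUE, reason = "")
}

# extend both ends of an ordered pixel path along the local tangent until
# leaving the foreground mask
extend_to_boundary <- function(path, mask) {
  extend_one <- function(path) {
    n <- nrow(path)
    k <- min(5, n - 1)
    tang <- path[n, ] - path[n - k, ]
    nt <- sqrt(sum(tang^2))
    if (nt < 1e-9) return(path)
    tang <- tang / nt
    pos <- path[n, ]
    added <- NULL
    for (s in seq_len(40)) {
      cand <- pos + 0.5 * tang
      i <- round(cand[2]); j <- round(cand[1])
      if (i < 1 || j < 1 || i > nrow(mask) || j > ncol(mask) ||
          !mask[i, j]) break
      pos <- cand
      added <- rbind(added, cand)
    }
    if (!is.null(added)) path <- rbind(path, added)
    path
  }
  path <- extend_one(path)
  path <- extend_one(path[nrow(path):1, , drop = FALSE])
  path
}

#' Resample an ordered path at equal arc-length intervals
#'
#' Divides the path into \code{n - 1} segments of equal arc length and
#' returns the \code{n} segment endpoints (the standard 13-point midline
#' uses 12 segments). Endpoints are preserved exactly.
#'
#' @param path m x 2 matrix of ordered coordinates.
#' @param n Number of output points (>= 2).
#' @return An n x 2 matrix.
#' @export
resample_midline <- function(path, n = 13) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  stopifnot(is.matrix(path), ncol(path) == 2, nrow(path) >= 2)
  d <- sqrt(rowSums(diff(path)^2))
  total <- sum(d)
  if (total <= 0) stop("path has zero arc length", call. = FALSE)
  s <- total * (seq_len(n) - 1) / (n - 1)
  out <- interp_polyline(path, s)
  out[1, ] <- path[1, ]
  out[n, ] <- path[nrow(path), ]
  colnames(out) <- c("x", "y")
  out
}

# smooth an ordered path with a small moving average, endpoints pinned
smooth_path <- function(path, w) {
  if (w <= 1 || nrow(path) < w + 2) return(path)
  out <- cbind(moving_average(path[, 1], w), moving_average(path[, 2], w))
  out[1, ] <- path[1, ]
  out[nrow(path), ] <- path[nrow(path), ]
  out
}

#' Map pixel-space points to plate coordinates
#'
#' Plate position = stage position + oriented, scaled offset of the pixel
#' point from the image center.
#'
#' @param pts_px m x 2 matrix of pixel coordinates (x right, y down,
#'   origin top-left, pixel centers at integers).
#' @param stage Numeric length-2 stage position, mm.
#' @param calibration A [calibration_info()].
#' @param frame_size Frame size in pixels, \code{c(width, height)}.
#' @return An m x 2 matrix of plate coordinates in mm (x right, y up).
#' @export
to_plate_coords <- function(pts_px, stage, calibration, frame_size) {
  stopifnot(inherits(calibration, "calibration_info"))
  if (length(frame_size) == 1) frame_size <- rep(frame_size, 2)
  cx <- (frame_size[1] + 1) / 2
  cy <- (frame_size[2] + 1) / 2
  sgn <- switch(calibration$axis_orientation,
                "+x+y" = c(1, 1), "+x-y" = c(1, -1),
                "-x+y" = c(-1, 1), "-x-y" = c(-1, -1))
  mm <- calibration$mm_per_pixel
  cbind(x = stage[1] + sgn[1] * (pts_px[, 1] - cx) * mm,
        y = stage[2] + sgn[2] * (pts_px[, 2] - cy) * mm)
}

#' Orient a pose series head-first
#'
#' Endpoint labels are first made temporally continuous (each frame keeps
#' the point order minimizing the frame-to-frame endpoint displacement),
#' then the global head/tail choice assigns "head" to the endpoint with the
#' larger mean instantaneous speed over the video — during both striding
#' and head sweeps the head moves faster than the tail. The attribute
#' \code{orientation_confidence} reflects the speed-ratio margin
#' (0 = arbitrary, as for a single-frame series).
#'
#' @param series A [pose_series()] with arbitrary endpoint order.
#' @return The series with point 1 = head, plus an
#'   \code{orientation_confidence} attribute in \code{[0, 1]}.
#' @export
orient_head_tail <- function(series) {
  stopifnot(inherits(series, "pose_series"))
  vi <- which(series$valid)
  if (length(vi) == 0) stop("empty series: no valid poses", call. = FALSE)
  P <- pose_points(series)
  flip_row <- function(v) {
    m <- matrix(v, ncol = 2, byrow = TRUE)
    as.vector(t(m[13:1, , drop = FALSE]))
  }
  # temporal continuity pass
  prev <- vi[1]
  for (i in vi[-1]) {
    e1 <- P[i, c(1, 2)]; e13 <- P[i, c(25, 26)]
    p1 <- P[prev, c(1, 2)]; p13 <- P[prev, c(25, 26)]
    d_keep <- sqrt(sum((e1 - p1)^2)) + sqrt(sum((e13 - p13)^2))
    d_flip <- sqrt(sum((e1 - p13)^2)) + sqrt(sum((e13 - p1)^2))
    if (d_flip < d_keep) P[i, ] <- flip_row(P[i, ])
    prev <- i
  }
  # global head/tail decision by mean endpoint speed
  conf <- 0
  if (length(vi) >= 2) {
    d1 <- sqrt(rowSums((P[vi[-1], c(1, 2), drop = FALSE] -
                        P[vi[-length(vi)], c(1, 2), drop = FALSE])^2))
    d13 <- sqrt(rowSums((P[vi[-1], c(25, 26), drop = FALSE] -
                         P[vi[-length(vi)], c(25, 26), drop = FALSE])^2))
    v1 <- mean(d1); v13 <- mean(d13)
    if (v13 > v1) P[vi, ] <- t(apply(P[vi, , drop = FALSE], 1, flip_row))
    conf <- if (v1 + v13 > 0) abs(v1 - v13) / (v1 + v13) else 0
  }
  series[, pose_cols()] <- P
  attr(series, "orientation_confidence") <- conf
  series
}

read_frame_input <- function(frames) {
  if (is.character(frames) && length(frames) == 1 && dir.exists(frames)) {
    files <- sort(list.files(frames, pattern = "\\.png$",
                             full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", frames,
                             call. = FALSE)
    list(n = length(files),
         get = function(i) {
           img <- png::readPNG(files[i])
           if (length(dim(img)) == 3) img <- img[, , 1]
           img
         })
  } else if (is.list(frames)) {
    list(n = length(frames), get = function(i) frames[[i]])
  } else stop("frames must be a directory path or a list of matrices",
              call. = FALSE)
}

#' Recognize a video: frames + stage log -> 13-point midline series
#'
#' Runs the full recognizer on an image sequence: per-frame binarization,
#' skeletonization and equal-arc-length resampling to 13 points; mapping
#' to plate coordinates through the stage log; and head/tail orientation.
#' Frames that fail (no component, implausible area, self-touching
#' topology, missing stage record) are carried as invalid gaps with a
#' reason code; a video with more than \code{invalid_warn_frac} invalid
#' frames is flagged.
#'
#' @param frames Directory of numbered grayscale PNGs, or a list of
#'   numeric matrices in \code{[0, 1]}.
#' @param stage_log Data frame (or TSV path) with columns
#'   \code{frame_index}, \code{time_s}, \code{stage_x_mm},
#'   \code{stage_y_mm}. Missing frame entries are interpolated for gaps of
#'   at most 2 frames; larger gaps invalidate the affected frames.
#' @param config A [run_config()]; supplies the calibration and all
#'   recognizer thresholds.
#' @return A [pose_series()] in plate mm with attributes
#'   \code{orientation_confidence}, \code{invalid_fraction} and
#'   \code{flagged} (TRUE when too many frames failed).
#' @export
recognize_video <- function(frames, stage_log, config = run_config()) {
  src <- read_frame_input(frames)
  if (is.character(stage_log)) stage_log <- read_stage_log(stage_log)
  n <- src$n
  calib <- calibration_info(config$mm_per_pixel, config$axis_orientation)
  # stage per frame, with short-gap interpolation
  idx_all <- seq_len(n)
  sx <- approx(stage_log$frame_index, stage_log$stage_x_mm, xout = idx_all,
               method = "constant", rule = 2, f = 0, ties = "ordered")$y
  sy <- approx(stage_log$frame_index, stage_log$stage_y_mm, xout = idx_all,
               method = "constant", rule = 2, f = 0, ties = "ordered")$y
  tt <- approx(stage_log$frame_index, stage_log$time_s, xout = idx_all,
               rule = 2, ties = "ordered")$y
  have <- idx_all %in% stage_log$frame_index
  gap_run <- rle(have)
  gap_ok <- rep(TRUE, n)
  pos <- 1
  for (k in seq_along(gap_run$lengths)) {
    len <- gap_run$lengths[k]
    if (!gap_run$values[k] && len > 2)
      gap_ok[pos:(pos + len - 1)] <- FALSE
    pos <- pos + len
  }
  pts <- matrix(NA_real_, n, 26)
  valid <- logical(n)
  reason <- character(n)
  fs <- NULL
  for (i in seq_len(n)) {
    if (!gap_ok[i]) { reason[i] <- "stage_gap"; next }
    img <- src$get(i)
    if (is.null(fs)) fs <- c(ncol(img), nrow(img))
    bin <- binarize_frame(img, config)
    if (!bin$valid) { reason[i] <- bin$reason; next }
    sk <- extract_skeleton(bin$mask, config)
    if (!sk$ok) { reason[i] <- sk$reason; next }
    mp <- tryCatch(resample_midline(sk$path, 13), error = function(e) NULL)
    if (is.null(mp)) { reason[i] <- "degenerate"; next }
    mm <- to_plate_coords(mp, c(sx[i], sy[i]), calib, fs)
    pts[i, ] <- as.vector(t(mm))
    valid[i] <- TRUE
  }
  if (!any(valid)) stop("empty series: no frame could be recognized",
                        call. = FALSE)
  series <- pose_series(frame = idx_all, time = tt, points = pts,
                        valid = valid, reason = reason,
                        frame_rate = config$frame_rate)
  series <- orient_head_tail(series)
  inv <- mean(!valid)
  attr(series, "invalid_fraction") <- inv
  attr(series, "flagged") <- inv > config$invalid_warn_frac
  attr(series, "mm_per_pixel") <- config$mm_per_pixel
  series
}
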