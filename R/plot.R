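#' Plot (or export) the track of one video
#'
#' Draws the center-point path with the confinement ring and the
#' direction-change points marked, the standard one-glance view of a
#' tracking session.
#'
#' @param series A [pose_series()].
#' @param config A [run_config()].
#' @param arena An [arena_geometry()]; default built from \code{config}.
#' @param file If non-NULL, write a PNG to this path instead of drawing on
#'   the current device.
#' @param width,height PNG size in pixels.
#' @return The [track_analysis()] result, invisibly.
#' @export
plot_track <- function(series, config = run_config(), arena = NULL,
                       file = NULL, width = 600, height = 600) {
  if (is.null(arena))
    arena <- arena_geometry(plate_radius = config$plate_radius,
                            ring_width = config$ring_width)
  tr <- track_analysis(series, config, arena)
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  cen <- point_xy(series, 7)
  R <- arena$plate_radius
  cc <- arena$plate_center
  th <- seq(0, 2 * pi, length.out = 256)
  plot(NA, xlim = cc[1] + c(-R, R) * 1.05, ylim = cc[2] + c(-R, R) * 1.05,
       asp = 1, xlab = "x (mm)", ylab = "y (mm)", main = "track")
  lines(cc[1] + R * cos(th), cc[2] + R * sin(th), col = "grey40")
  Ri <- R - arena$ring_width
  lines(cc[1] + Ri * cos(th), cc[2] + Ri * sin(th), col = "grey70")
  lines(cen[, 1], cen[, 2], col = "blue")
  pts <- tr$changes$points
  if (!is.null(pts) && any(pts$change))
    points(pts$x[pts$change], pts$y[pts$change], col = "red", pch = 19,
           cex = 0.8)
  invisible(tr)
}
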