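# Text interchange formats: the per-frame 13-point "points" TSV (the
# recognizer's output and the analyzers' input), the per-frame metrics
# TSV, and the ground-truth export of the simulator.

#' Read / write a midline points file
#'
#' Tab-separated text, one row per frame: \code{frame_index},
#' \code{time_s}, \code{valid}, then \code{x1, y1, ..., x13, y13} in
#' plate-frame mm ('.' decimal separator, header row). Invalid frames
#' carry \code{NA} coordinates.
#'
#' @param series A [pose_series()].
#' @param path File path.
#' @param frame_rate Frame rate used when reading (stored on the series).
#' @return \code{read_points} returns a [pose_series()].
#' @export
write_points <- function(series, path) {
  stopifnot(inherits(series, "pose_series"))
  df <- data.frame(frame_index = series$frame, time_s = series$time,
                   valid = as.integer(series$valid),
                   series[, pose_cols()], check.names = FALSE)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path, frame_rate = NULL) {
  df <- tryCatch(read.delim(path, check.names = FALSE,
                            na.strings = c("NA", "")),
                 error = function(e)
                   stop("cannot parse points file ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  need <- c("frame_index", "time_s", "valid", pose_cols())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("points file ", path, " lacks columns: ",
         paste(head(miss, 4), collapse = ", "),
         if (length(miss) > 4) " ..." else "", call. = FALSE)
  for (cn in need) {
    if (!is.numeric(df[[cn]]))
      stop("points file ", path, ": non-numeric data in column '", cn,
           "' (line ",
           which(is.na(suppressWarnings(as.numeric(df[[cn]]))) &
                 !is.na(df[[cn]]))[1] + 1, ")", call. = FALSE)
  }
  if (is.null(frame_rate)) {
    dt <- diff(df$time_s)
    frame_rate <- if (length(dt)) 1 / median(dt[dt > 0]) else 1
  }
  pose_series(frame = df$frame_index, time = df$time_s,
              points = as.matrix(df[, pose_cols()]),
              valid = df$valid > 0 &
                complete.cases(df[, pose_cols()]),
              frame_rate = frame_rate)
}

#' Export the per-frame metrics table
#'
#' The viewer-style per-frame export: time, body length, the 13 per-point
#' speeds, bend angles and flags, striding and inside masks.
#'
#' @param metrics Data frame from [frame_metrics()] (with
#'   \code{striding}/\code{inside} filled by [summarize_video()] or
#'   manually).
#' @param path File path.
#' @export
write_metrics <- function(metrics, path) {
  df <- metrics
  names(df)[names(df) == "time"] <- "time_s"
  names(df)[names(df) == "length"] <- "length_mm"
  for (cn in c("valid", "head_bending", "body_bending", "bending",
               "striding", "inside"))
    if (cn %in% names(df)) df[[cn]] <- as.integer(df[[cn]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export simulator ground truth
#'
#' Writes the per-frame labels as TSV and the stride/run tables plus the
#' true parameter vector as one JSON summary.
#'
#' @param truth A \code{ground_truth} from [simulate_crawl()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lab <- truth$labels
  lab$striding <- as.integer(lab$striding)
  write.table(lab, file.path(dir, "truth_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  js <- list(strides = truth$strides, runs = truth$runs,
             summary = as.list(truth$summary),
             config = unclass(truth$config))
  jsonlite::write_json(js, file.path(dir, "truth_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Write a batch summary table
#'
#' Stable tab-separated schema: metadata columns, then the parameters of
#' [parameter_names()] with inside/outside variants and raw totals.
#'
#' @param summaries Data frame from [batch_process()].
#' @param path File path.
#' @export
write_summary_table <- function(summaries, path) {
  write.table(summaries, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
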