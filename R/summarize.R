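# Per-video parameter vectors, batch tables, coefficient of variation and
# same-day-control normalization for phenotypic profiling.

#' Names of the per-video locomotion parameters
#'
#' The 21-parameter panel: shape (body length, contracted/extended length,
#' bending times), peristalsis (speed, time striding, striding speed,
#' stride duration/distance, contraction/extension rates), stamina (stride
#' count, run distance/duration/stride count, run count) and track
#' (distance, direction change, time inside). Time parameters are
#' fractions in \code{[0, 1]}; counts are per minute.
#'
#' @param variants If TRUE, also return the \code{_inside}/\code{_outside}
#'   variant column names (computed for the parameters measured per frame
#'   or per stride).
#' @return Character vector of column names.
#' @export
parameter_names <- function(variants = FALSE) {
  base <- c("body_length", "body_length_contracted", "body_length_extended",
            "time_head_bending", "time_body_bending", "time_bending",
            "speed", "time_striding", "speed_striding", "stride_duration",
            "stride_distance", "contraction_rate", "extension_rate",
            "stride_count", "run_distance", "run_duration",
            "run_stride_count", "run_count",
            "distance", "direction_change", "time_inside")
  if (!variants) return(base)
  v <- c("speed", "time_striding", "speed_striding", "stride_duration",
         "stride_distance", "contraction_rate", "extension_rate",
         "time_head_bending", "time_body_bending", "time_bending")
  c(base, paste0(rep(v, each = 2), c("_inside", "_outside")))
}

masked_stride_stats <- function(strides, series, keep_frames) {
  if (nrow(strides) == 0) return(rep(NA_real_, 4))
  in_mask <- vapply(seq_len(nrow(strides)), function(k) {
    fidx <- which(series$time >= strides$t_start[k] - 1e-9 &
                  series$time <= strides$t_end[k] + 1e-9)
    keep <- keep_frames[fidx]
    mean(keep, na.rm = TRUE) > 0.5
  }, logical(1))
  st <- strides[in_mask, , drop = FALSE]
  if (nrow(st) == 0) return(rep(NA_real_, 4))
  c(mean(st$duration), mean(st$distance),
    mean(st$contraction_rate), mean(st$extension_rate))
}

#' Summarize one video into the per-video parameter vector
#'
#' Runs the kinematics, stride and track engines and averages into the
#' 21-parameter panel. Per-frame parameters are averaged over valid frames
#' (striding-only subsets where the parameter is defined only during
#' strides); per-video parameters are computed once. Parameters that
#' cannot be measured (e.g. stride duration with zero strides) are
#' reported as missing, never zero. The \code{_inside}/\code{_outside}
#' variants repeat the frame- and stride-level parameters restricted to
#' frames away from vs close to the confinement ring.
#'
#' @param series A [pose_series()].
#' @param config A [run_config()].
#' @param arena An [arena_geometry()]; default built from \code{config}.
#' @param metadata Named list merged into the output row (e.g.
#'   \code{video_id}, \code{date}, \code{genotype}, \code{sex},
#'   \code{stage}).
#' @return A one-row data frame of class \code{video_summary}: metadata,
#'   \code{n_frames}, \code{n_valid_frames}, \code{error} flag, the
#'   parameters of [parameter_names()] with inside/outside variants, and
#'   raw totals \code{stride_total}, \code{run_total}.
#' @export
summarize_video <- function(series, config = run_config(), arena = NULL,
                            metadata = list()) {
  meta <- list(video_id = NA_character_, date = NA_character_,
               genotype = NA_character_, sex = NA_character_,
               stage = NA_character_)
  meta[names(metadata)] <- metadata
  span <- nrow(series) / frame_rate_of(series)
  empty <- function(err) {
    out <- data.frame(meta, n_frames = nrow(series), n_valid_frames = 0L,
                      error = err, stringsAsFactors = FALSE)
    for (p in parameter_names(variants = TRUE)) out[[p]] <- NA_real_
    out$stride_total <- NA_real_; out$run_total <- NA_real_
    class(out) <- c("video_summary", "data.frame")
    out
  }
  if (!any(series$valid)) return(empty(TRUE))

  mx <- frame_metrics(series, config)
  sa <- stride_analysis(series, config)
  tr <- track_analysis(series, config, arena)
  mx$striding <- sa$striding
  mx$inside <- tr$inside$inside
  ok <- series$valid

  fr_mean <- function(x, mask = ok) {
    m <- mask & ok & !is.na(x)
    if (!any(m)) NA_real_ else mean(x[m])
  }
  strides <- sa$strides
  runs <- sa$runs
  n_str <- nrow(strides)

  out <- data.frame(meta, n_frames = nrow(series),
                    n_valid_frames = sum(ok), error = FALSE,
                    stringsAsFactors = FALSE)
  out$body_length <- fr_mean(mx$length)
  out$body_length_contracted <- if (n_str) mean(strides$length_min) else NA_real_
  out$body_length_extended <- if (n_str) mean(strides$length_max) else NA_real_
  out$time_head_bending <- fr_mean(as.numeric(mx$head_bending))
  out$time_body_bending <- fr_mean(as.numeric(mx$body_bending))
  out$time_bending <- fr_mean(as.numeric(mx$bending))
  out$speed <- if (config$speed_mode == "total")
    tr$distance$mm / span else fr_mean(mx$speed)
  out$time_striding <- fr_mean(as.numeric(mx$striding))
  out$speed_striding <- fr_mean(mx$speed, mask = mx$striding)
  out$stride_duration <- if (n_str) mean(strides$duration) else NA_real_
  out$stride_distance <- if (n_str) mean(strides$distance) else NA_real_
  out$contraction_rate <- if (n_str) mean(strides$contraction_rate) else NA_real_
  out$extension_rate <- if (n_str) mean(strides$extension_rate) else NA_real_
  out$stride_count <- n_str / span * 60
  out$run_distance <- if (nrow(runs)) mean(runs$distance) else NA_real_
  out$run_duration <- if (nrow(runs)) mean(runs$duration) else NA_real_
  out$run_stride_count <- if (nrow(runs)) mean(runs$stride_count) else NA_real_
  out$run_count <- nrow(runs) / span * 60
  out$distance <- tr$distance$mm_per_min
  out$direction_change <- tr$changes$fraction
  out$time_inside <- tr$inside$fraction

  for (side in c("inside", "outside")) {
    mask <- if (side == "inside") tr$inside$inside else !tr$inside$inside
    mask[is.na(mask)] <- FALSE
    sfx <- paste0("_", side)
    out[[paste0("speed", sfx)]] <- fr_mean(mx$speed, mask)
    out[[paste0("time_striding", sfx)]] <-
      fr_mean(as.numeric(mx$striding), mask)
    out[[paste0("speed_striding", sfx)]] <-
      fr_mean(mx$speed, mask & mx$striding)
    out[[paste0("time_head_bending", sfx)]] <-
      fr_mean(as.numeric(mx$head_bending), mask)
    out[[paste0("time_body_bending", sfx)]] <-
      fr_mean(as.numeric(mx$body_bending), mask)
    out[[paste0("time_bending", sfx)]] <-
      fr_mean(as.numeric(mx$bending), mask)
    ss <- masked_stride_stats(strides, series, mask)
    out[[paste0("stride_duration", sfx)]] <- ss[1]
    out[[paste0("stride_distance", sfx)]] <- ss[2]
    out[[paste0("contraction_rate", sfx)]] <- ss[3]
    out[[paste0("extension_rate", sfx)]] <- ss[4]
  }
  out$stride_total <- n_str
  out$run_total <- nrow(runs)
  if (isTRUE(attr(series, "flagged"))) out$error <- TRUE
  class(out) <- c("video_summary", "data.frame")
  out
}

#' Batch-process a folder of midline point files
#'
#' Reads every points TSV in a folder, summarizes each video, and returns
#' one table with a row per video in deterministic (filename-sorted)
#' order. Unparseable files are logged and skipped, not fatal.
#'
#' @param folder Directory containing points TSV files (see
#'   [write_points()]).
#' @param metadata Optional data frame with a \code{video_id} column
#'   (matched against file names without extension) and e.g. \code{date},
#'   \code{genotype} columns, merged into the result.
#' @param config A [run_config()].
#' @param arena An [arena_geometry()] or NULL.
#' @param pattern Regular expression selecting the points files.
#' @return A data frame with one row per successfully parsed video; the
#'   \code{skipped} attribute lists files that failed to parse.
#' @export
batch_process <- function(folder, metadata = NULL, config = run_config(),
                          arena = NULL, pattern = "\\.tsv$") {
  files <- sort(list.files(folder, pattern = pattern, full.names = TRUE))
  files <- files[basename(files) != "stage_log.tsv"]
  if (!length(files)) {
    warning("no points files found in ", folder)
    return(data.frame())
  }
  rows <- list()
  skipped <- character(0)
  for (f in files) {
    vid <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      series <- read_points(f, frame_rate = config$frame_rate)
      md <- list(video_id = vid)
      if (!is.null(metadata) && vid %in% metadata$video_id) {
        mrow <- metadata[metadata$video_id == vid, , drop = FALSE]
        for (cn in setdiff(names(mrow), "video_id"))
          md[[cn]] <- mrow[[cn]][1]
      }
      summarize_video(series, config, arena, metadata = md)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, basename(f))
    else rows[[length(rows) + 1]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "skipped") <- skipped
  out
}

#' Coefficient of variation
#'
#' The ratio of the sample standard deviation to the mean, as a
#' percentage. Undefined (NA) for fewer than two finite values or a zero
#' mean.
#'
#' @param values Numeric vector.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(2, 4))  # 47.14
#' @export
coefficient_of_variation <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  100 * sd(v) / m
}

#' Coefficient-of-variation table for a batch summary
#'
#' @param summaries A summary table from [batch_process()] or rows of
#'   [summarize_video()].
#' @param params Parameter columns to evaluate.
#' @return Data frame with \code{parameter}, \code{mean}, \code{sd},
#'   \code{cv} (percent), \code{n}.
#' @export
cv_table <- function(summaries, params = parameter_names()) {
  params <- intersect(params, names(summaries))
  do.call(rbind, lapply(params, function(p) {
    v <- summaries[[p]][is.finite(summaries[[p]])]
    data.frame(parameter = p,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               cv = coefficient_of_variation(v),
               n = length(v))
  }))
}

#' Normalize parameter values by same-day controls
#'
#' Divides each animal's parameter values by the mean of the control
#' animals tracked on the same date, canceling day effects (age of the
#' cohort, temperature, experimenter). Animals on dates without a control
#' group get missing normalized values; parameters whose control mean is
#' zero are skipped with a warning.
#'
#' @param summaries Summary table with \code{genotype} and \code{date}
#'   columns (see [batch_process()]).
#' @param control_genotype Genotype label of the control group.
#' @param params Parameter columns to normalize.
#' @return The summary table with the parameter columns replaced by
#'   control-normalized values; attribute \code{skipped_params} lists
#'   parameters skipped for zero control means, \code{missing_dates} the
#'   dates lacking controls.
#' @export
normalize_by_control <- function(summaries,
                                 control_genotype = "control",
                                 params = parameter_names()) {
  stopifnot(all(c("genotype", "date") %in% names(summaries)))
  params <- intersect(params, names(summaries))
  ctrl <- summaries[summaries$genotype == control_genotype, , drop = FALSE]
  if (nrow(ctrl) == 0)
    stop("no animals of control genotype '", control_genotype, "'",
         call. = FALSE)
  out <- summaries
  skipped <- character(0)
  missing_dates <- setdiff(unique(summaries$date), unique(ctrl$date))
  if (length(missing_dates))
    message("no same-date controls for: ",
            paste(missing_dates, collapse = ", "))
  for (p in params) {
    cm <- tapply(ctrl[[p]], ctrl$date, function(v) mean(v, na.rm = TRUE))
    if (any(!is.na(cm) & cm == 0)) {
      warning("control mean of '", p, "' is zero on some dates; skipped")
      skipped <- c(skipped, p)
      out[[p]] <- NA_real_
      next
    }
    denom <- cm[as.character(summaries$date)]
    out[[p]] <- summaries[[p]] / as.numeric(denom)
  }
  attr(out, "skipped_params") <- skipped
  attr(out, "missing_dates") <- missing_dates
  out
}

#' Phenotypic profile matrix
#'
#' Assembles genotype-by-parameter profiles from control-normalized
#' summaries: each cell is the mean (or the SD) of the normalized values
#' of one parameter in one genotype. Under self-normalization the control
#' row of the mean profile is identically 1.
#'
#' @param normalized Output of [normalize_by_control()].
#' @param params Parameter columns.
#' @param value \code{"mean"} for normalized means, \code{"sd"} for
#'   normalized standard deviations.
#' @return Numeric matrix, rows = genotypes, columns = parameters.
#' @export
profile_matrix <- function(normalized, params = parameter_names(),
                           value = c("mean", "sd")) {
  value <- match.arg(value)
  params <- intersect(params, names(normalized))
  gt <- unique(normalized$genotype)
  fun <- if (value == "mean") function(v) mean(v, na.rm = TRUE)
         else function(v) sd(v, na.rm = TRUE)
  m <- matrix(NA_real_, length(gt), length(params),
              dimnames = list(gt, params))
  for (g in gt) {
    sub <- normalized[normalized$genotype == g, , drop = FALSE]
    for (p in params) {
      v <- sub[[p]][is.finite(sub[[p]])]
      m[g, p] <- if (length(v)) fun(v) else NA_real_
    }
  }
  m
}

#' Pearson correlation between phenotypic profiles
#'
#' Similarity of genotype rows of a [profile_matrix()]; profiles that are
#' near-constant (e.g. a self-normalized control, identically 1) have no
#' variance, and their correlation with any profile is reported as 1 when
#' compared against an identical profile and NA otherwise.
#'
#' @param profiles Matrix from [profile_matrix()].
#' @return Genotype-by-genotype correlation matrix.
#' @export
profile_correlation <- function(profiles) {
  g <- nrow(profiles)
  out <- matrix(NA_real_, g, g,
                dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    a <- profiles[i, ]; b <- profiles[j, ]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2) next
    if (isTRUE(all.equal(a[ok], b[ok]))) { out[i, j] <- 1; next }
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) next
    out[i, j] <- cor(a[ok], b[ok])
  }
  out
}
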