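#' Configuration for the synthetic peristaltic crawler
#'
#' Parameterizes the ground-truth crawler used for validation. Defaults are
#' anchored to wild-type (Canton-S) wandering third-instar larvae: body
#' length 4.34 mm, stride period 1.61 s, stride distance 0.89 mm, 76% of
#' time spent striding, about 9 runs in a 4-minute session, recorded at
#' 7.5 frames/s on a 10 cm plate with a 1.5-cm confinement ring. The length
#' oscillation amplitude defaults to half the contracted-to-extended span
#' (4.12 to 4.63 mm).
#'
#' @param mean_length Mean body length, mm.
#' @param length_amplitude Half the peak-to-peak body-length oscillation
#'   during a stride, mm. Must satisfy \code{mean_length > 2*length_amplitude}.
#' @param stride_period Duration of one peristalsis cycle, s.
#' @param stride_distance Net advance of the body center per cycle, mm.
#' @param time_striding_target Target fraction of time spent striding, in
#'   \code{[0, 1]}.
#' @param n_runs_target Target number of runs (maximal bouts of continuous
#'   striding) over the session.
#' @param head_sweep_amplitude Peak head-sweep angle during pauses, degrees.
#' @param run_turn_sd SD of the per-stride heading change during runs,
#'   degrees.
#' @param extension_fraction Fraction of the stride cycle spent extending
#'   (the rest contracting); values below 0.5 make extension faster than
#'   contraction, as observed in real larvae.
#' @param arena_radius Plate radius, mm (10 cm dish = 50 mm).
#' @param ring_width Width of the confinement ring on the outer rim, mm.
#' @param frame_rate Frames per second.
#' @param duration Session duration, s.
#' @param noise_sd_position SD of isotropic Gaussian positional noise added
#'   to every midline point, mm.
#' @param sweep_period Period of the sinusoidal head sweep during pauses, s.
#' @param rng_seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class \code{sim_config}.
#' @seealso [simulate_crawl()], [render_frames()]
#' @export
sim_config <- function(mean_length = 4.34,
                       length_amplitude = 0.255,
                       stride_period = 1.61,
                       stride_distance = 0.89,
                       time_striding_target = 0.76,
                       n_runs_target = 9,
                       head_sweep_amplitude = 60,
                       run_turn_sd = 8,
                       extension_fraction = 0.5,
                       arena_radius = 50,
                       ring_width = 15,
                       frame_rate = 7.5,
                       duration = 240,
                       noise_sd_position = 0.01,
                       sweep_period = 4,
                       rng_seed = 1L) {
  cfg <- list(
    mean_length = mean_length, length_amplitude = length_amplitude,
    stride_period = stride_period, stride_distance = stride_distance,
    time_striding_target = time_striding_target,
    n_runs_target = n_runs_target,
    head_sweep_amplitude = head_sweep_amplitude,
    run_turn_sd = run_turn_sd,
    extension_fraction = extension_fraction,
    arena_radius = arena_radius, ring_width = ring_width,
    frame_rate = frame_rate, duration = duration,
    noise_sd_position = noise_sd_position,
    sweep_period = sweep_period,
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(what) {
    stop("invalid sim_config: violated invariant '", what, "'", call. = FALSE)
  }
  with(cfg, {
    if (!(length_amplitude > 0)) fail("length_amplitude > 0")
    if (!(mean_length > 2 * length_amplitude))
      fail("mean_length > 2*length_amplitude")
    if (!(frame_rate > 0)) fail("frame_rate > 0")
    if (!(stride_period > 2 / frame_rate))
      fail("stride_period > 2/frame_rate")
    if (time_striding_target < 0 || time_striding_target > 1)
      fail("0 <= time_striding_target <= 1")
    if (!(ring_width < arena_radius)) fail("ring_width < arena_radius")
    if (!(ring_width > 0)) fail("ring_width > 0")
    if (!(duration > 0)) fail("duration > 0")
    if (extension_fraction <= 0 || extension_fraction >= 1)
      fail("0 < extension_fraction < 1")
    if (head_sweep_amplitude < 0 || head_sweep_amplitude > 180)
      fail("0 <= head_sweep_amplitude <= 180")
    if (noise_sd_position < 0) fail("noise_sd_position >= 0")
    if (n_runs_target < 1) fail("n_runs_target >= 1")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Default analysis settings. Every threshold used anywhere in the pipeline
# lives here so that one config file governs all stages.
run_config_defaults <- function() {
  list(
    # recognizer
    mm_per_pixel = 0.05,
    frame_rate = 7.5,
    threshold = NA_real_,        # NA = per-frame Otsu
    min_area = 0.5,              # mm^2, smallest plausible larva silhouette
    max_area = 20,               # mm^2
    prune_frac = 0.15,           # skeleton branches below this fraction of
                                 # total length are pruned
    path_smooth = 5,             # px window for smoothing the pixel path
    axis_orientation = "+x-y",   # image-to-plate axis mapping
    invalid_warn_frac = 0.2,
    # kinematics
    speed_window = 0.5,          # s, centered displacement window
    bend_threshold = 45,         # degrees
    # stride engine
    smooth_length = 0.4,         # s moving average on body length
    min_prominence_frac = 0.03,  # of mean body length
    period_min = 0.4,            # s
    period_max = 5,              # s
    min_stride_displacement = 0.1, # mm center advance per cycle
    max_gap = 0.5,               # s, stride gap merged into one run
    require_speed_symmetry = FALSE,
    # track engine
    sample_interval = 1,         # s, track subsampling for turning angles
    turn_threshold = 60,         # degrees
    track_smooth = 0.5,          # s moving average on center position
    inside_margin = NA_real_,    # mm; NA = half mean body length
    plate_radius = 50,           # mm
    ring_width = 15,             # mm
    # aggregate
    speed_mode = "frame"         # "frame": mean per-frame speed;
                                 # "total": displacement sum / total time
  )
}

#' Analysis configuration
#'
#' Collects every threshold and window used by the recognizer, kinematics,
#' stride, track and aggregation stages. Call with no arguments for the
#' defaults; pass named values to override. Unknown names are rejected.
#'
#' @param ... Named overrides of the default settings; see Details.
#' @details Settings (units, defaults): \code{mm_per_pixel} (mm, 0.05),
#'   \code{frame_rate} (fps, 7.5), \code{threshold} (gray level; NA = Otsu
#'   per frame), \code{min_area}/\code{max_area} (mm^2, 0.5/20),
#'   \code{prune_frac} (0.15 of skeleton length), \code{path_smooth}
#'   (px, 5), \code{axis_orientation} (one of \code{"+x+y"}, \code{"+x-y"},
#'   \code{"-x+y"}, \code{"-x-y"}), \code{speed_window} (s, 0.5),
#'   \code{bend_threshold} (deg, 45), \code{smooth_length} (s, 0.4),
#'   \code{min_prominence_frac} (0.03 of mean length), \code{period_min}/
#'   \code{period_max} (s, 0.4/5), \code{min_stride_displacement} (mm, 0.1),
#'   \code{max_gap} (s, 0.5), \code{sample_interval} (s, 1),
#'   \code{turn_threshold} (deg, 60), \code{track_smooth} (s, 0.5),
#'   \code{inside_margin} (mm; NA = half mean body length),
#'   \code{plate_radius}/\code{ring_width} (mm, 50/15), \code{speed_mode}
#'   (\code{"frame"} or \code{"total"}), \code{require_speed_symmetry}
#'   (logical, FALSE), \code{invalid_warn_frac} (0.2).
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all run_config() arguments must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown run_config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(dots)] <- dots
  }
  numeric_keys <- setdiff(names(cfg),
                          c("axis_orientation", "speed_mode",
                            "require_speed_symmetry"))
  for (k in numeric_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  if (!cfg$axis_orientation %in% c("+x+y", "+x-y", "-x+y", "-x-y"))
    stop("axis_orientation must be one of +x+y, +x-y, -x+y, -x-y",
         call. = FALSE)
  if (!cfg$speed_mode %in% c("frame", "total"))
    stop("speed_mode must be 'frame' or 'total'", call. = FALSE)
  cfg$require_speed_symmetry <- isTRUE(as.logical(cfg$require_speed_symmetry))
  stopifnot(cfg$mm_per_pixel > 0, cfg$frame_rate > 0)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write an analysis configuration file
#'
#' Plain-text \code{key = value} format, one setting per line; \code{#}
#' starts a comment. Unknown keys are rejected with an error naming the key.
#'
#' @param path File path.
#' @return \code{read_run_config} returns a \code{run_config};
#'   \code{write_run_config} returns \code{path} invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'",
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub("^\"|\"$", "", val)
    num <- suppressWarnings(as.numeric(val))
    vals[[key]] <- if (!is.na(num)) num else
      if (val %in% c("true", "false", "TRUE", "FALSE"))
        as.logical(toupper(val)) else if (val == "NA") NA_real_ else val
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A \code{run_config} object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(v) {
    if (is.character(v)) sprintf("\"%s\"", v)
    else if (is.logical(v)) tolower(as.character(v))
    else if (is.na(v)) "NA"
    else format(v, scientific = FALSE)
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(unclass(config), fmt, character(1))), path)
  invisible(path)
}
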