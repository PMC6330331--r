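#' Pipeline configuration
#'
#' Collects every threshold and tolerance of the preprocessing, detection,
#' metric and scene-cut stages, with defaults equal to the values used
#' throughout the package's reference analysis. Units are noted per field.
#'
#' @param blink_speed_threshold deg/s; samples flanking a blink gap are
#'   invalidated while local speed exceeds this.
#' @param blink_edge_cap_ms ms; maximum extent of blink-edge invalidation
#'   per side.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window
#'   length (samples).
#' @param speed_method `"central"` (central differences of the smoothed
#'   positions) or `"sgolay"` (the filter's analytic derivative).
#' @param onset_threshold deg/s; saccade onset requires speed above this.
#' @param min_above_ms ms; minimum time speed must stay above threshold.
#' @param min_magnitude,max_magnitude degrees; accepted magnitude range
#'   (exclusive bounds).
#' @param min_duration_ms ms; accepted saccades are strictly longer.
#' @param max_initial_speed deg/ms; speed at the onset sample must be below.
#' @param max_terminal_speed deg/ms; speed at the offset sample must be below.
#' @param quartile_fraction the speed at one quarter of the duration must be
#'   at least this fraction of the peak speed.
#' @param curvature_variant `"as_written"` (full second difference) or
#'   `"perpendicular"` (orthogonal component only).
#' @param model_speed `"discrete"` (model velocity through the same
#'   difference operator as the data) or `"analytic"` (closed form).
#' @param cut_k_sd cut threshold is mean + `cut_k_sd` * sd of the
#'   frame-difference metric.
#' @param cut_min_gap_frames candidate cuts closer than this keep only the
#'   larger metric.
#' @param fade_reject drop runs of near-equal suprathreshold transitions
#'   (gradual fades).
#' @param seed integer seed recorded with the run.
#' @return A named list of class `saccurv_config`.
#' @export
run_config <- function(blink_speed_threshold = 30,
                       blink_edge_cap_ms = 50,
                       sg_order = 3L,
                       sg_window = 15L,
                       speed_method = "central",
                       onset_threshold = 30,
                       min_above_ms = 10,
                       min_magnitude = 1,
                       max_magnitude = 40,
                       min_duration_ms = 15,
                       max_initial_speed = 0.075,
                       max_terminal_speed = 0.3,
                       quartile_fraction = 0.15,
                       curvature_variant = "as_written",
                       model_speed = "discrete",
                       cut_k_sd = 1,
                       cut_min_gap_frames = 5L,
                       fade_reject = TRUE,
                       seed = 1L) {
  cfg <- list(
    blink_speed_threshold = blink_speed_threshold,
    blink_edge_cap_ms = blink_edge_cap_ms,
    sg_order = as.integer(sg_order), sg_window = as.integer(sg_window),
    speed_method = match.arg(speed_method, c("central", "sgolay")),
    onset_threshold = onset_threshold, min_above_ms = min_above_ms,
    min_magnitude = min_magnitude, max_magnitude = max_magnitude,
    min_duration_ms = min_duration_ms,
    max_initial_speed = max_initial_speed,
    max_terminal_speed = max_terminal_speed,
    quartile_fraction = quartile_fraction,
    curvature_variant = match.arg(curvature_variant, c("as_written", "perpendicular")),
    model_speed = match.arg(model_speed, c("discrete", "analytic")),
    cut_k_sd = cut_k_sd, cut_min_gap_frames = as.integer(cut_min_gap_frames),
    fade_reject = isTRUE(fade_reject), seed = as.integer(seed)
  )
  num <- c(
    "blink_speed_threshold", "blink_edge_cap_ms", "sg_window",
    "onset_threshold", "min_above_ms", "min_magnitude", "max_magnitude",
    "min_duration_ms", "max_initial_speed", "max_terminal_speed",
    "quartile_fraction", "cut_min_gap_frames"
  )
  bad <- num[vapply(num, function(f) !is.numeric(cfg[[f]]) || cfg[[f]] <= 0, logical(1))]
  if (length(bad)) stop_spec(paste0("config thresholds must be strictly positive: ", paste(bad, collapse = ", ")))
  structure(cfg, class = "saccurv_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) stop_format(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `saccurv_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
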