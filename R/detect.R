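#' Segment saccade candidates from a speed trace
#'
#' A saccade begins when speed exceeds the onset threshold and stays above
#' it for at least `min_above_ms`; it ends at the last sample before speed
#' drops back below the threshold. Each maximal suprathreshold run becomes
#' one candidate; candidates are non-overlapping and time-ordered. Event
#' duration follows the sample-count convention
#' (`n_samples * dt`), so a 12-sample run at 1 kHz lasts 12 ms.
#'
#' @param trace a preprocessed [gaze_trace()] with a `speed` column
#'   (see [preprocess_gaze()]).
#' @param onset_threshold deg/s; comparison is strictly greater.
#' @param min_above_ms minimum suprathreshold time, ms.
#' @return A tibble of candidate events with kinematics and orientation.
#' @export
segment_saccades <- function(trace, onset_threshold = 30, min_above_ms = 10) {
  if (!"speed" %in% names(trace)) stop_format("trace has no speed column; run preprocess_gaze() first")
  dt <- trace_dt(trace)
  thr <- onset_threshold / 1000 # deg/ms
  runs <- logical_runs(trace$speed > thr)
  if (nrow(runs)) {
    runs <- runs[(runs$end - runs$start + 1L) * dt >= min_above_ms, , drop = FALSE]
  }
  if (!nrow(runs)) {
    return(complete_saccade_cols(tibble(onset_idx = integer(), offset_idx = integer()))[0, ])
  }
  ev <- pmap(list(runs$start, runs$end), function(i0, i1) {
    dx <- trace$x[i1] - trace$x[i0]
    dy <- trace$y[i1] - trace$y[i0]
    idx <- i0:i1
    tibble(
      onset_idx = i0, offset_idx = i1,
      onset_ms = trace$time_ms[i0], offset_ms = trace$time_ms[i1],
      duration_ms = (i1 - i0 + 1L) * dt,
      magnitude = sqrt(dx^2 + dy^2),
      path_length = sum(sqrt(diff(trace$x[idx])^2 + diff(trace$y[idx])^2)),
      peak_velocity = max(trace$speed[idx]),
      direction = wrap_angle(atan2(dy, dx) * 180 / pi)
    )
  })
  ev <- list_rbind(ev)
  cls <- classify_orientation(ev$direction)
  ev$orientation <- cls$orientation
  ev$leftward <- cls$leftward
  ev$downward <- cls$downward
  ev$trace_id <- trace_id(trace)
  ev$session_offset_ms <- session_offset(trace) + ev$onset_ms
  ev
}

saccade_rejection_reasons <- c(
  "boundary", "magnitude_high", "magnitude_low", "duration_short",
  "initial_velocity_high", "terminal_velocity_high", "slow_first_quartile"
)

#' Apply saccade inclusion rules
#'
#' A candidate is accepted iff all of the following hold: magnitude
#' strictly between `min_magnitude` and `max_magnitude` (1 and 40 degrees:
#' the display diagonal bounds real saccades above, microsaccades are
#' excluded below); duration strictly greater than `min_duration_ms`;
#' speed at the onset sample below `max_initial_speed` and at the offset
#' sample below `max_terminal_speed`; and speed at the sample one quarter
#' into the event at least `quartile_fraction` of the peak (removing
#' uniform low-velocity profiles such as pursuit fragments). Candidates
#' touching the trace boundary are rejected outright. Each rejected
#' candidate carries exactly one reason: the first failing rule.
#'
#' @param candidates output of [segment_saccades()].
#' @param trace the speed-bearing trace the candidates came from.
#' @param config a [run_config()].
#' @return The candidates with `accepted` and `rejection_reason` columns.
#' @export
apply_saccade_filters <- function(candidates, trace, config = run_config()) {
  if (!nrow(candidates)) {
    candidates$accepted <- logical()
    candidates$rejection_reason <- character()
    return(candidates)
  }
  n <- nrow(trace)
  dur_samples <- candidates$offset_idx - candidates$onset_idx + 1L
  q_idx <- candidates$onset_idx + floor(dur_samples / 4)
  sp_on <- trace$speed[candidates$onset_idx]
  sp_off <- trace$speed[candidates$offset_idx]
  sp_q <- trace$speed[q_idx]
  reason <- rep(NA_character_, nrow(candidates))
  fails <- cbind(
    boundary = candidates$onset_idx == 1L | candidates$offset_idx == n,
    magnitude_high = !(candidates$magnitude < config$max_magnitude),
    magnitude_low = !(candidates$magnitude > config$min_magnitude),
    duration_short = !(candidates$duration_ms > config$min_duration_ms),
    initial_velocity_high = !(sp_on < config$max_initial_speed),
    terminal_velocity_high = !(sp_off < config$max_terminal_speed),
    slow_first_quartile = !(sp_q >= config$quartile_fraction * candidates$peak_velocity)
  )
  first_fail <- apply(fails, 1L, function(f) if (any(f)) colnames(fails)[which(f)[1L]] else NA_character_)
  candidates$accepted <- is.na(first_fail)
  candidates$rejection_reason <- first_fail
  candidates
}

#' Classify saccade orientation and direction sense
#'
#' Orientation is horizontal when the path direction is within 5 degrees
#' of 0 or 180 (inclusive), vertical when within 22 degrees of 90 or 270,
#' and oblique otherwise. Under the y-up convention a saccade is leftward
#' when its direction lies strictly inside (90, 270) and downward when
#' strictly inside (180, 360).
#'
#' @param direction direction(s) in degrees, 0 = rightward, 90 = upward.
#' @return A tibble with columns `orientation`, `leftward`, `downward`.
#' @export
#' @examples
#' classify_orientation(c(3, 85, 45, 200))
classify_orientation <- function(direction) {
  d <- wrap_angle(direction)
  horizontal <- angle_dist(d, 0) <= 5 | angle_dist(d, 180) <= 5
  vertical <- angle_dist(d, 90) <= 22 | angle_dist(d, 270) <= 22
  tibble(
    orientation = ifelse(horizontal, "horizontal", ifelse(vertical, "vertical", "oblique")),
    leftward = d > 90 & d < 270,
    downward = d > 180 & d < 360
  )
}

#' Detect saccades in a preprocessed trace
#'
#' Runs [segment_saccades()] and [apply_saccade_filters()]. All candidates
#' are returned; accepted events have `accepted = TRUE`, the rest carry a
#' rejection reason.
#'
#' @param trace a preprocessed [gaze_trace()] with `speed`.
#' @param config a [run_config()].
#' @return A saccade-event tibble.
#' @export
#' @examples
#' ses <- make_session(random_session_spec(n_saccades = 5, seed = 3))
#' ev <- detect_saccades(preprocess_gaze(ses$trace))
#' sum(ev$accepted)
detect_saccades <- function(trace, config = run_config()) {
  cand <- segment_saccades(trace,
    onset_threshold = config$onset_threshold,
    min_above_ms = config$min_above_ms
  )
  apply_saccade_filters(cand, trace, config)
}

#' Main-sequence summary of detected saccades
#'
#' The saccadic main sequence is the stereotyped power-law relation
#' between peak velocity and magnitude; on bi-logarithmic axes it is
#' near linear. Fits ordinary least squares of log10(peak velocity) on
#' log10(magnitude) over the accepted events.
#'
#' @param events a saccade-event tibble (accepted events are used).
#' @return A `main_sequence_fit` with the per-event table and the fit;
#'   supports [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @export
main_sequence <- function(events) {
  ev <- events[is.na(events$accepted) | events$accepted, , drop = FALSE]
  if (nrow(ev) < 3L) stop_insufficient("need at least 3 accepted saccades for a main sequence")
  df <- tibble(
    magnitude = ev$magnitude, duration_ms = ev$duration_ms,
    peak_velocity = ev$peak_velocity,
    log_magnitude = log10(ev$magnitude),
    log_peak_velocity = log10(ev$peak_velocity)
  )
  if (sd(df$log_magnitude) == 0) stop_spec("degenerate predictor: all magnitudes identical")
  fit <- lm(log_peak_velocity ~ log_magnitude, data = df)
  structure(list(data = df, fit = fit), class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cf <- coef(x$fit)
  cat(sprintf(
    "# main sequence: log10(peak vel) = %.3f + %.3f log10(magnitude), n = %d\n",
    cf[1], cf[2], nrow(x$data)
  ))
  invisible(x)
}

#' @method tidy main_sequence_fit
#' @export
tidy.main_sequence_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "log_magnitude"),
    estimate = unname(s[, 1]), std_error = unname(s[, 2]),
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' @method glance main_sequence_fit
#' @export
glance.main_sequence_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = nrow(x$data), r_squared = s$r.squared, sigma = s$sigma,
    slope = coef(x$fit)[[2]], intercept = coef(x$fit)[[1]]
  )
}

#' @method autoplot main_sequence_fit
#' @export
autoplot.main_sequence_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$magnitude, .data$peak_velocity * 1000)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "magnitude (deg)", y = "peak velocity (deg/s)",
      title = "saccadic main sequence"
    ) +
    ggplot2::theme_minimal()
}
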