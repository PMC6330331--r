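#' Construct a gaze trace
#'
#' A gaze trace is a tibble with one row per sample and columns `time_ms`
#' (strictly increasing, uniform step), `x` and `y` (eye position in degrees
#' of visual angle; x positive rightward, y positive upward), and `valid`
#' (FALSE where the tracker reported missing data, e.g. during blinks).
#' The sampling rate (Hz), a trace identifier and the offset of the first
#' sample from the start of the session are carried as attributes.
#'
#' @param time_ms numeric vector of sample times in milliseconds.
#' @param x,y numeric vectors of eye position in degrees.
#' @param valid logical vector; FALSE marks tracker-reported missing samples.
#' @param trace_id character label for the trace.
#' @param session_offset_ms offset (ms) of `time_ms[1]` from session start.
#'
#' @return A `gaze_trace` tibble.
#' @export
#' @examples
#' tr <- gaze_trace(time_ms = 0:99, x = seq(0, 1, length.out = 100), y = 0)
#' sampling_rate(tr)
gaze_trace <- function(time_ms, x, y, valid = TRUE,
                       trace_id = "trace", session_offset_ms = 0) {
  n <- length(time_ms)
  x <- rep_len(as.double(x), n)
  y <- rep_len(as.double(y), n)
  valid <- rep_len(as.logical(valid), n)
  out <- new_gaze_trace(tibble(
    time_ms = as.double(time_ms), x = x, y = y, valid = valid
  ), trace_id = trace_id, session_offset_ms = session_offset_ms)
  validate_gaze_trace(out)
}

new_gaze_trace <- function(df, trace_id = "trace", session_offset_ms = 0,
                           sampling_rate = NULL) {
  df <- as_tibble(df)
  if (is.null(sampling_rate)) {
    dt <- diff(df$time_ms)
    sampling_rate <- if (length(dt)) 1000 / stats::median(dt) else NA_real_
  }
  structure(df,
    class = c("gaze_trace", class(tibble())),
    trace_id = trace_id,
    session_offset_ms = session_offset_ms,
    sampling_rate = sampling_rate
  )
}

validate_gaze_trace <- function(tr) {
  if (nrow(tr) < 2L) stop_insufficient("a gaze trace needs at least 2 samples")
  need <- c("time_ms", "x", "y", "valid")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop_format(paste0("gaze trace missing columns: ", paste(miss, collapse = ", ")))
  dt <- diff(tr$time_ms)
  if (any(dt <= 0)) stop_format("sample times must be strictly increasing")
  step <- dt[1L]
  if (any(abs(dt - step) > 1e-9 * max(step, 1))) {
    stop_format("sampling step is not uniform (tolerance 1e-9 relative)")
  }
  tr
}

#' @rdname gaze_trace
#' @param trace a `gaze_trace`.
#' @export
sampling_rate <- function(trace) attr(trace, "sampling_rate")

#' @rdname gaze_trace
#' @export
trace_id <- function(trace) attr(trace, "trace_id")

#' @rdname gaze_trace
#' @export
session_offset <- function(trace) attr(trace, "session_offset_ms")

# sampling step in ms
trace_dt <- function(trace) 1000 / sampling_rate(trace)

# carry gaze_trace attributes onto a modified copy of its data
rebuild_trace <- function(df, template) {
  new_gaze_trace(df,
    trace_id = trace_id(template),
    session_offset_ms = session_offset(template),
    sampling_rate = sampling_rate(template)
  )
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf(
    "# gaze trace '%s': %d samples @ %.6g Hz, %.1f%% valid\n",
    trace_id(x), nrow(x), sampling_rate(x), 100 * mean(x$valid)
  ))
  NextMethod()
}

#' Plot a gaze trace
#'
#' Shows horizontal and vertical eye position over time; samples flagged
#' invalid are drawn in a muted colour. If a `speed` column is present a
#' third panel shows it.
#'
#' @param object a `gaze_trace`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot gaze_trace
#' @export
autoplot.gaze_trace <- function(object, ...) {
  value_cols <- intersect(c("x", "y", "speed"), names(object))
  long <- tidyr::pivot_longer(as_tibble(object),
    cols = all_of(value_cols),
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel, levels = value_cols)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$valid, group = 1), linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70"), guide = "none") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(
      x = "time (ms)", y = NULL,
      title = paste0("gaze trace: ", trace_id(object))
    ) +
    ggplot2::theme_minimal()
}
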