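#' Blink-edge excision
#'
#' Samples the tracker already flagged invalid stay invalid. Valid samples
#' adjacent to each gap are additionally invalidated, marching outward
#' while the local sample-to-sample speed exceeds `speed_threshold`
#' (tracker traces show high-velocity artifacts flanking blinks), up to
#' `cap_ms` per side.
#'
#' @param trace a [gaze_trace()].
#' @param speed_threshold deg/s.
#' @param cap_ms maximum extent of the outward march per side, ms.
#' @return The trace with an enlarged invalid mask.
#' @export
excise_blinks <- function(trace, speed_threshold = 30, cap_ms = 50) {
  if (!any(trace$valid)) stop_insufficient("trace has no valid samples")
  dt <- trace_dt(trace)
  thr <- speed_threshold / 1000 # deg/ms
  n <- nrow(trace)
  valid <- trace$valid
  if (all(valid)) return(trace)
  step_speed <- sqrt(diff(trace$x)^2 + diff(trace$y)^2) / dt # between i and i+1
  cap <- max(1L, floor(cap_ms / dt))
  gaps <- logical_runs(!valid)
  for (g in seq_len(nrow(gaps))) {
    j <- gaps$end[g] + 1L # trailing edge, march right
    while (j <= n && j <= gaps$end[g] + cap && valid[j] &&
           j < n && step_speed[j] > thr) {
      valid[j] <- FALSE
      j <- j + 1L
    }
    j <- gaps$start[g] - 1L # leading edge, march left
    while (j >= 1L && j >= gaps$start[g] - cap && valid[j] &&
           j > 1L && step_speed[j - 1L] > thr) {
      valid[j] <- FALSE
      j <- j - 1L
    }
  }
  out <- as_tibble(trace)
  out$valid <- valid
  rebuild_trace(out, trace)
}

#' Cubic-spline interpolation over invalid gaps
#'
#' Interior gaps are filled with a natural cubic spline fit through the
#' valid samples; gaps at the trace edges (no bracketing data) hold the
#' nearest valid value. All samples are marked valid afterwards and an
#' `interpolated` column records which were replaced.
#'
#' @param trace a [gaze_trace()].
#' @return The gap-filled trace.
#' @export
interpolate_gaps <- function(trace) {
  n <- nrow(trace)
  valid <- trace$valid
  if (sum(valid) < 4L) stop_insufficient("need at least 4 valid samples to interpolate")
  out <- as_tibble(trace)
  out$interpolated <- !valid
  if (!all(valid)) {
    iv <- which(valid)
    first_v <- iv[1L]
    last_v <- iv[length(iv)]
    fill <- which(!valid)
    interior <- fill[fill > first_v & fill < last_v]
    for (col in c("x", "y")) {
      v <- out[[col]]
      if (length(interior)) {
        v[interior] <- spline(
          x = trace$time_ms[iv], y = trace[[col]][iv],
          xout = trace$time_ms[interior], method = "natural"
        )$y
      }
      v[fill[fill < first_v]] <- trace[[col]][first_v]
      v[fill[fill > last_v]] <- trace[[col]][last_v]
      out[[col]] <- v
    }
    out$valid <- TRUE
  }
  rebuild_trace(out, trace)
}

#' Savitzky-Golay smoothing of eye position
#'
#' x and y are filtered independently with a polynomial least-squares
#' (Savitzky-Golay) FIR filter. Near the trace edges the filter's
#' off-centre projection rows are used (a polynomial fit to the available
#' window, no zero padding), which avoids spurious edge velocities. A
#' filter of order >= 3 reproduces cubic signals exactly.
#'
#' @param trace a [gaze_trace()].
#' @param order polynomial order.
#' @param window window length in samples (odd).
#' @return The smoothed trace.
#' @export
smooth_gaze <- function(trace, order = 3, window = 15) {
  if (nrow(trace) < window) stop_insufficient("trace shorter than the smoothing window")
  out <- as_tibble(trace)
  out$x <- as.numeric(signal::sgolayfilt(out$x, p = order, n = window))
  out$y <- as.numeric(signal::sgolayfilt(out$y, p = order, n = window))
  rebuild_trace(out, trace)
}

#' Gaze speed as the norm of the velocity vector
#'
#' Velocity is the first derivative of eye position with respect to time,
#' estimated per axis by central differences (one-sided at the trace
#' ends) on the sampling grid; speed is its Euclidean norm in deg/ms.
#' `method = "sgolay"` instead uses the analytic derivative of the
#' Savitzky-Golay polynomial fit.
#'
#' @param trace a (smoothed) [gaze_trace()].
#' @param method `"central"` or `"sgolay"`.
#' @param order,window Savitzky-Golay parameters for `method = "sgolay"`.
#' @return The trace with a `speed` column (deg/ms).
#' @export
compute_speed <- function(trace, method = c("central", "sgolay"),
                          order = 3, window = 15) {
  method <- match.arg(method)
  dt <- trace_dt(trace)
  out <- as_tibble(trace)
  if (method == "central") {
    vx <- central_diff(out$x, dt)
    vy <- central_diff(out$y, dt)
  } else {
    vx <- as.numeric(signal::sgolayfilt(out$x, p = order, n = window, m = 1)) / dt
    vy <- as.numeric(signal::sgolayfilt(out$y, p = order, n = window, m = 1)) / dt
  }
  out$speed <- sqrt(vx^2 + vy^2)
  rebuild_trace(out, trace)
}

#' Full preprocessing chain
#'
#' Blink-edge excision, cubic-spline gap interpolation, Savitzky-Golay
#' smoothing and speed computation, in that fixed order.
#'
#' @param trace a raw [gaze_trace()].
#' @param config a [run_config()].
#' @return The preprocessed trace with `speed` and `interpolated` columns.
#' @export
#' @examples
#' ses <- make_session(random_session_spec(n_saccades = 3, seed = 2))
#' pre <- preprocess_gaze(ses$trace)
#' max(pre$speed)
preprocess_gaze <- function(trace, config = run_config()) {
  trace <- excise_blinks(trace,
    speed_threshold = config$blink_speed_threshold,
    cap_ms = config$blink_edge_cap_ms
  )
  trace <- interpolate_gaps(trace)
  trace <- smooth_gaze(trace, order = config$sg_order, window = config$sg_window)
  compute_speed(trace,
    method = config$speed_method,
    order = config$sg_order, window = config$sg_window
  )
}
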