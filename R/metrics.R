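#' Median pointwise curvature of a sampled path
#'
#' For a path sampled at points \eqn{(x_t, y_t)}, \eqn{t = 1..T}, the
#' pointwise curvature at interior samples \eqn{t = 2..T-1} is the
#' Euclidean norm of the second difference normalized by the total path
#' length:
#' \deqn{k_t = \frac{\sqrt{(x_{t+1}-2x_t+x_{t-1})^2 +
#'   (y_{t+1}-2y_t+y_{t-1})^2}}
#'   {\sum_t \sqrt{(x_t-x_{t-1})^2+(y_t-y_{t-1})^2}}}
#' and the path's curvature score `k` is the median of the \eqn{k_t}.
#' Both numerator and denominator are lengths, so `k` is dimensionless and
#' invariant under rotation, translation and uniform scaling.
#'
#' The `"as_written"` variant uses the full second difference, which also
#' picks up tangential acceleration: a straight path traversed at varying
#' speed gets \eqn{k_t > 0}. The `"perpendicular"` variant replaces the
#' numerator by the component of the second difference orthogonal to the
#' local chord \eqn{(x_{t+1}-x_{t-1}, y_{t+1}-y_{t-1})}, which is zero on
#' any straight path. `"as_written"` is the default.
#'
#' @param path a data frame with columns `x` and `y` (degrees), or a
#'   two-column matrix.
#' @param variant `"as_written"` or `"perpendicular"`.
#' @return A list of class `curvature_result` with elements `pointwise`
#'   (the \eqn{k_t} series) and `k` (their median).
#' @export
#' @examples
#' straight <- data.frame(x = 0:9, y = 0)
#' pointwise_curvature(straight)$k # 0
pointwise_curvature <- function(path, variant = c("as_written", "perpendicular")) {
  variant <- match.arg(variant)
  if (is.matrix(path)) path <- tibble(x = path[, 1], y = path[, 2])
  x <- path$x
  y <- path$y
  T_ <- length(x)
  if (T_ < 4L) stop_insufficient("curvature needs at least 4 samples")
  dx <- diff(x)
  dy <- diff(y)
  total_len <- sum(sqrt(dx^2 + dy^2))
  if (total_len == 0) abort("degenerate path of zero length", class = "saccurv_error_degenerate")
  i <- 2:(T_ - 1L)
  d2x <- x[i + 1L] - 2 * x[i] + x[i - 1L]
  d2y <- y[i + 1L] - 2 * y[i] + y[i - 1L]
  if (variant == "as_written") {
    num <- sqrt(d2x^2 + d2y^2)
  } else {
    cx <- x[i + 1L] - x[i - 1L]
    cy <- y[i + 1L] - y[i - 1L]
    cn <- sqrt(cx^2 + cy^2)
    # orthogonal component = |cross product| / |chord|; zero chord keeps full norm
    num <- ifelse(cn > 0, abs(d2x * cy - d2y * cx) / cn, sqrt(d2x^2 + d2y^2))
  }
  kt <- num / total_len
  structure(
    list(pointwise = kt, k = median(kt), variant = variant),
    class = "curvature_result"
  )
}

#' @export
print.curvature_result <- function(x, ...) {
  cat(sprintf(
    "# curvature (%s): k = %.4g over %d interior samples\n",
    x$variant, x$k, length(x$pointwise)
  ))
  invisible(x)
}

#' Fit the compressed exponential model to one saccade
#'
#' The displacement series is the Euclidean distance of each event sample
#' from the onset-sample position, with time measured from onset. The
#' three-parameter compressed exponential ([saccade_position()]) is fit to
#' it by bounded nonlinear least squares (initialized at p1 = event
#' magnitude, p2 = duration / 2, p3 = 2; bounds p1 in (0, 3 x magnitude],
#' p2 in (0, 3 x duration], p3 in \[0.5, 10\]; up to 200 iterations,
#' relative tolerance 1e-10, no random restarts).
#'
#' The velocity-profile deviation is the root-mean-square difference, in
#' deg/ms, between the measured speed over the event and the fitted
#' model's velocity. Though the model is fit in the position domain,
#' deviations are scored in the velocity domain, where profile anomalies
#' are most visible. With `model_speed = "discrete"` (default) the model
#' velocity is evaluated by applying the same finite-difference operator
#' to the fitted position curve that produced the measured speed, so the
#' score is exactly zero for data that follow the model and is not
#' inflated by shared differentiation bias; `"analytic"` evaluates the
#' closed-form derivative ([saccade_velocity()]) instead.
#'
#' @param event one row of a saccade-event tibble.
#' @param trace the preprocessed [gaze_trace()] (with `speed`) the event
#'   was detected in.
#' @param model_speed `"discrete"` or `"analytic"`.
#' @return A `velocity_profile_fit`: parameters `p1` (degrees), `p2` (ms),
#'   `p3`, `deviation` (deg/ms RMSE), `converged`, `n_samples`, and a
#'   `profile` tibble with per-sample measured and fitted values. Supports
#'   `tidy()`, `glance()` and `autoplot()`.
#' @export
fit_velocity_profile <- function(event, trace, model_speed = c("discrete", "analytic")) {
  model_speed <- match.arg(model_speed)
  if (!"speed" %in% names(trace)) stop_format("trace has no speed column; run preprocess_gaze() first")
  dt <- trace_dt(trace)
  i0 <- which.min(abs(trace$time_ms - event$onset_ms))
  i1 <- which.min(abs(trace$time_ms - event$offset_ms))
  if (i1 - i0 + 1L < 8L) stop_insufficient("velocity-profile fit needs at least 8 samples")
  idx <- i0:i1
  t_rel <- trace$time_ms[idx] - trace$time_ms[i0]
  d <- sqrt((trace$x[idx] - trace$x[i0])^2 + (trace$y[idx] - trace$y[i0])^2)
  mag <- max(d[length(d)], 1e-6)
  dur <- t_rel[length(t_rel)] + dt
  start <- c(p1 = mag, p2 = dur / 2, p3 = 2)
  lower <- c(1e-9, 1e-9, 0.5)
  upper <- c(3 * mag, 3 * dur, 10)
  df <- tibble(t = t_rel, d = d)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      d ~ p1 * (1 - exp(-(t / p2)^p3)),
      data = df, start = as.list(start),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10, ptol = 1e-10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    pars <- start
    converged <- FALSE
  } else {
    pars <- coef(fit)
    converged <- isTRUE(fit$convInfo$isConv) ||
      isTRUE(fit$convInfo$finIter < 200)
  }
  sp_meas <- trace$speed[idx]
  sp_model <- model_speed_series(
    t_rel, idx, nrow(trace), dt,
    pars[["p1"]], pars[["p2"]], pars[["p3"]],
    method = model_speed
  )
  deviation <- sqrt(mean((sp_meas - sp_model)^2))
  structure(list(
    p1 = unname(pars[["p1"]]), p2 = unname(pars[["p2"]]), p3 = unname(pars[["p3"]]),
    deviation = deviation, converged = converged, n_samples = length(idx),
    model_speed = model_speed,
    profile = tibble(
      t_ms = t_rel, displacement = d,
      fitted_displacement = saccade_position(t_rel, pars[["p1"]], pars[["p2"]], pars[["p3"]]),
      speed = sp_meas, fitted_speed = sp_model
    )
  ), class = "velocity_profile_fit")
}

# model velocity evaluated on the sampling grid with the same difference
# stencil as compute_speed: central in the interior, one-sided at the
# trace boundaries; the model position is 0 before onset.
model_speed_series <- function(t_rel, idx, n_trace, dt, p1, p2, p3,
                               method = c("discrete", "analytic")) {
  method <- match.arg(method)
  if (method == "analytic") {
    return(saccade_velocity(t_rel, p1, p2, p3))
  }
  f <- function(t) saccade_position(t, p1, p2, p3)
  m <- length(t_rel)
  out <- numeric(m)
  for (k in seq_len(m)) {
    j <- idx[k]
    tk <- t_rel[k]
    if (j == 1L) {
      out[k] <- (f(tk + dt) - f(tk)) / dt
    } else if (j == n_trace) {
      out[k] <- (f(tk) - f(tk - dt)) / dt
    } else {
      out[k] <- (f(tk + dt) - f(tk - dt)) / (2 * dt)
    }
  }
  out
}

#' @export
print.velocity_profile_fit <- function(x, ...) {
  cat(sprintf(
    "# compressed exponential fit: p1 = %.3f deg, p2 = %.3f ms, p3 = %.3f; deviation = %.4g deg/ms (%s)\n",
    x$p1, x$p2, x$p3, x$deviation, if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @method tidy velocity_profile_fit
#' @export
tidy.velocity_profile_fit <- function(x, ...) {
  tibble(
    term = c("p1", "p2", "p3"),
    estimate = c(x$p1, x$p2, x$p3),
    unit = c("deg", "ms", "1")
  )
}

#' @method glance velocity_profile_fit
#' @export
glance.velocity_profile_fit <- function(x, ...) {
  tibble(
    p1 = x$p1, p2 = x$p2, p3 = x$p3,
    deviation = x$deviation, converged = x$converged, n = x$n_samples
  )
}

#' @method autoplot velocity_profile_fit
#' @export
autoplot.velocity_profile_fit <- function(object, ...) {
  pr <- object$profile
  long <- tidyr::pivot_longer(pr, c("speed", "fitted_speed"),
    names_to = "series", values_to = "v"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$v, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(speed = "black", fitted_speed = "firebrick"),
      labels = c(speed = "measured", fitted_speed = "model fit")
    ) +
    ggplot2::labs(
      x = "time since onset (ms)", y = "speed (deg/ms)", colour = NULL,
      title = sprintf("velocity profile (deviation %.3g deg/ms)", object$deviation)
    ) +
    ggplot2::theme_minimal()
}

#' Attach curvature and velocity-profile metrics to detected saccades
#'
#' For every accepted event, computes the median pointwise curvature of
#' the event's trajectory samples and fits the compressed exponential
#' velocity-profile model, filling the `curvature`, `p1`, `p2`, `p3`,
#' `deviation` and `converged` columns. Rejected events keep `NA`.
#'
#' @param events saccade-event tibble from [detect_saccades()].
#' @param trace the preprocessed trace (with `speed`).
#' @param config a [run_config()] (curvature variant, model-speed method).
#' @return The events tibble with metric columns filled.
#' @export
#' @examples
#' ses <- make_session(random_session_spec(n_saccades = 5, seed = 4))
#' pre <- preprocess_gaze(ses$trace)
#' ev <- add_saccade_metrics(detect_saccades(pre), pre)
#' ev[ev$accepted, c("magnitude", "curvature", "deviation")]
add_saccade_metrics <- function(events, trace, config = run_config()) {
  for (col in c("curvature", "p1", "p2", "p3", "deviation")) {
    if (!col %in% names(events)) events[[col]] <- NA_real_
  }
  if (!"converged" %in% names(events)) events$converged <- NA
  for (r in seq_len(nrow(events))) {
    if (!isTRUE(events$accepted[r])) next
    i0 <- which.min(abs(trace$time_ms - events$onset_ms[r]))
    i1 <- which.min(abs(trace$time_ms - events$offset_ms[r]))
    idx <- i0:i1
    if (length(idx) >= 4L) {
      k <- tryCatch(
        pointwise_curvature(
          tibble(x = trace$x[idx], y = trace$y[idx]),
          variant = config$curvature_variant
        )$k,
        error = function(e) NA_real_
      )
      events$curvature[r] <- k
    }
    if (length(idx) >= 8L) {
      vf <- tryCatch(
        fit_velocity_profile(events[r, ], trace, model_speed = config$model_speed),
        error = function(e) NULL
      )
      if (!is.null(vf)) {
        events$p1[r] <- vf$p1
        events$p2[r] <- vf$p2
        events$p3[r] <- vf$p3
        events$deviation[r] <- vf$deviation
        events$converged[r] <- vf$converged
      }
    }
  }
  events
}
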