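#' Frame-difference metric for shot-boundary detection
#'
#' For each consecutive frame pair the metric is the log of the mean
#' absolute pixel difference (the pixelwise sum of absolute differences
#' normalized by the frame's pixel count), with a small epsilon guarding
#' `log(0)`:
#' \deqn{m_i = \log\left(\epsilon + \frac{1}{N}\sum_{p} |F_{i+1,p} - F_{i,p}|\right)}
#'
#' @param clip a [clip_frames()] object.
#' @param eps guard added inside the log; default 1e-6.
#' @return A tibble with columns `transition` (index i of the pair
#'   i, i+1), `metric`, and `time_ms` of the later frame.
#' @export
frame_diff_metric <- function(clip, eps = 1e-6) {
  stopifnot(inherits(clip, "clip_frames"))
  fr <- clip$frames
  n <- length(fr)
  m <- vapply(seq_len(n - 1L), function(i) {
    log(eps + mean(abs(fr[[i + 1L]] - fr[[i]])))
  }, numeric(1))
  tibble(
    transition = seq_len(n - 1L),
    metric = m,
    time_ms = seq_len(n - 1L) * 1000 / clip$frame_rate
  )
}

#' Detect scene cuts with an adaptive threshold
#'
#' Transitions whose frame-difference metric exceeds the clip's mean plus
#' `k_sd` standard deviations are cut candidates. Gradual fades produce
#' runs of three or more consecutive suprathreshold transitions with
#' near-equal metrics (relative spread below 10%); with
#' `fade_reject = TRUE` such runs are dropped. Of candidates closer than
#' `min_gap_frames` only the larger metric is kept. A zero-variance
#' metric series yields no cuts. The cut time is that of the later frame
#' of the transition pair.
#'
#' @param metric output of [frame_diff_metric()] (or any tibble with
#'   `transition`, `metric`, `time_ms`).
#' @param k_sd threshold multiplier on the standard deviation.
#' @param min_gap_frames minimum separation between reported cuts.
#' @param fade_reject drop gradual-ramp candidate runs.
#' @return A `scene_cuts` object: the metric series, the threshold, the
#'   accepted cuts (frame index of the later frame and its time), and the
#'   transitions rejected as fades.
#' @export
#' @examples
#' out <- make_clip(40, cut_frames = c(10, 25),
#'                  base_levels = c(50, 120, 200), noise_sd = 2, seed = 1)
#' detect_scene_cuts(frame_diff_metric(out$clip))$cuts
detect_scene_cuts <- function(metric, k_sd = 1, min_gap_frames = 5,
                              fade_reject = TRUE) {
  m <- metric$metric
  if (length(m) < 2L) stop_insufficient("metric series needs at least 2 transitions")
  if (any(diff(metric$transition) <= 0)) stop_format("transitions must be increasing")
  mu <- mean(m)
  sdev <- sd(m)
  threshold <- mu + k_sd * sdev
  cand <- if (sdev == 0) integer() else which(m > threshold)
  rejected_fades <- integer()
  if (fade_reject && length(cand)) {
    runs <- logical_runs(seq_along(m) %in% cand)
    for (r in seq_len(nrow(runs))) {
      span <- runs$start[r]:runs$end[r]
      if (length(span) >= 3L) {
        spread <- (max(m[span]) - min(m[span])) / max(abs(m[span]), 1e-12)
        if (spread < 0.1) rejected_fades <- c(rejected_fades, span)
      }
    }
    cand <- setdiff(cand, rejected_fades)
  }
  if (length(cand) > 1L) {
    keep <- logical(length(cand))
    for (i in order(m[cand], decreasing = TRUE)) {
      if (!any(keep & abs(cand - cand[i]) < min_gap_frames)) keep[i] <- TRUE
    }
    cand <- sort(cand[keep])
  }
  structure(list(
    metric = metric,
    threshold = threshold,
    cuts = tibble(
      transition = cand,
      frame = metric$transition[cand] + 1L, # later frame of the pair
      time_ms = metric$time_ms[cand]
    ),
    rejected_fades = tibble(
      transition = sort(unique(rejected_fades)),
      time_ms = metric$time_ms[sort(unique(rejected_fades))]
    )
  ), class = "scene_cuts")
}

#' @export
print.scene_cuts <- function(x, ...) {
  cat(sprintf(
    "# scene cuts: %d accepted (threshold %.3f), %d transitions rejected as fades\n",
    nrow(x$cuts), x$threshold, nrow(x$rejected_fades)
  ))
  if (nrow(x$cuts)) print(x$cuts)
  invisible(x)
}

#' @method autoplot scene_cuts
#' @export
autoplot.scene_cuts <- function(object, ...) {
  ggplot2::ggplot(object$metric, ggplot2::aes(.data$transition, .data$metric)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(
      data = object$metric[object$metric$transition %in% object$cuts$transition, ],
      colour = "firebrick", size = 1.6
    ) +
    ggplot2::labs(
      x = "frame transition", y = "log mean |frame difference|",
      title = "frame-difference metric and detected cuts"
    ) +
    ggplot2::theme_minimal()
}

#' Flag saccades in flight at a scene cut
#'
#' A saccade is "in flight" at a cut when some cut time lies inside its
#' onset-offset interval (closed on both ends). Events and cuts must share
#' a time base (ms from session start); pass `use_session_time = TRUE`
#' (default) to compare against the events' `session_offset_ms` clock, or
#' `FALSE` to use trace-local `onset_ms`/`offset_ms`.
#'
#' @param events saccade-event tibble.
#' @param cuts a `scene_cuts` object or a numeric vector of cut times (ms).
#' @param use_session_time logical, see above.
#' @return The events with `inflight_cut` set.
#' @export
flag_inflight <- function(events, cuts, use_session_time = TRUE) {
  cut_times <- if (inherits(cuts, "scene_cuts")) cuts$cuts$time_ms else as.numeric(cuts)
  if (is.unsorted(cut_times)) stop_format("cut times must be ordered")
  if (!nrow(events)) {
    events$inflight_cut <- logical()
    return(events)
  }
  onset <- if (use_session_time && "session_offset_ms" %in% names(events)) {
    events$session_offset_ms
  } else {
    events$onset_ms
  }
  offset <- onset + (events$offset_ms - events$onset_ms)
  events$inflight_cut <- vapply(seq_len(nrow(events)), function(i) {
    any(cut_times >= onset[i] & cut_times <= offset[i])
  }, logical(1))
  events
}
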