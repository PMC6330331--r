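#' Sample a single synthetic saccade trajectory
#'
#' The along-track displacement follows the compressed exponential model
#' ([saccade_position()]); trajectory curvature is injected as a symmetric
#' quadratic bump perpendicular to the chord, `bow * 4 s (1 - s)` with
#' `s = f(t)/p1`, which is zero at both endpoints and peaks mid-flight.
#' The bump is a generative stand-in chosen for being single-parameter,
#' endpoint-preserving and monotone in measured curvature; it is not a
#' physiological model of curved saccades. Sampling stops at the first
#' sample at or beyond 99.9% of the amplitude.
#'
#' @param magnitude saccade amplitude `p1`, degrees (> 0).
#' @param direction chord direction, degrees (0 = rightward, 90 = upward,
#'   counterclockwise).
#' @param p2 time scale, ms (> 0).
#' @param p3 shape parameter (> 0).
#' @param bow_amplitude signed peak perpendicular deviation, degrees;
#'   positive bows counterclockwise from the chord.
#' @param start_x,start_y starting position, degrees.
#' @param rate sampling rate, Hz.
#' @return A tibble with columns `t_ms`, `x`, `y`.
#' @export
#' @examples
#' path <- make_saccade_trajectory(5, direction = 0, p2 = 10, p3 = 2)
#' tail(path, 1) # end-to-end displacement close to 5 degrees
make_saccade_trajectory <- function(magnitude, direction = 0, p2 = 10, p3 = 2,
                                    bow_amplitude = 0,
                                    start_x = 0, start_y = 0, rate = 1000) {
  if (magnitude <= 0 || p2 <= 0 || p3 <= 0) stop_spec("magnitude, p2 and p3 must be > 0")
  if (rate <= 0) stop_spec("sampling rate must be > 0")
  dt <- 1000 / rate
  t_end <- saccade_model_duration(p2, p3)
  t <- seq(0, by = dt, length.out = ceiling(t_end / dt) + 1L)
  along <- saccade_position(t, magnitude, p2, p3)
  s <- along / magnitude
  perp <- bow_amplitude * 4 * s * (1 - s)
  th <- direction * pi / 180
  tibble(
    t_ms = t,
    x = start_x + along * cos(th) - perp * sin(th),
    y = start_y + along * sin(th) + perp * cos(th)
  )
}

#' Specify a synthetic gaze session
#'
#' A session spec fixes everything [make_session()] needs: total duration,
#' sampling rate, a saccade list, blink and pursuit schedules, noise levels
#' and a seed. Saccades chain spatially: each starts where the previous one
#' (or pursuit) ended. Events must not overlap in time (blinks are padded
#' by the 5 flanking edge-spike samples on each side).
#'
#' @param duration_ms total session length, ms.
#' @param sampling_rate Hz.
#' @param saccades tibble with columns `onset_ms`, `magnitude`, `direction`,
#'   `p2`, `p3`, `bow_amplitude`.
#' @param blinks tibble with columns `start_ms`, `duration_ms`; samples in
#'   the gap are marked invalid and the 5 samples flanking each side get
#'   40-100 deg/s position excursions (tracker-artifact emulation).
#' @param pursuits tibble with columns `start_ms`, `duration_ms`,
#'   `velocity` (deg/s) and `direction` (degrees): constant-velocity drift.
#' @param fixation_noise_sd degrees; i.i.d. positional jitter added during
#'   fixations only.
#' @param noise_sd degrees; i.i.d. measurement noise added to every sample.
#' @param start_x,start_y initial fixation position, degrees.
#' @param seed integer; fixes all randomness in [make_session()].
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(duration_ms, sampling_rate = 1000,
                         saccades = NULL, blinks = NULL, pursuits = NULL,
                         fixation_noise_sd = 0, noise_sd = 0,
                         start_x = 0, start_y = 0, seed = 1L) {
  empty_sac <- tibble(
    onset_ms = double(), magnitude = double(), direction = double(),
    p2 = double(), p3 = double(), bow_amplitude = double()
  )
  saccades <- as_tibble(saccades %||% empty_sac)
  blinks <- as_tibble(blinks %||% tibble(start_ms = double(), duration_ms = double()))
  pursuits <- as_tibble(pursuits %||% tibble(
    start_ms = double(), duration_ms = double(),
    velocity = double(), direction = double()
  ))
  if (fixation_noise_sd < 0 || noise_sd < 0) stop_spec("noise sds must be >= 0")
  spec <- structure(list(
    duration_ms = duration_ms, sampling_rate = sampling_rate,
    saccades = saccades, blinks = blinks, pursuits = pursuits,
    fixation_noise_sd = fixation_noise_sd, noise_sd = noise_sd,
    start_x = start_x, start_y = start_y, seed = as.integer(seed)
  ), class = "session_spec")
  validate_session_spec(spec)
}

validate_session_spec <- function(spec) {
  dt <- 1000 / spec$sampling_rate
  spans <- list()
  if (nrow(spec$saccades)) {
    dur <- saccade_model_duration(spec$saccades$p2, spec$saccades$p3)
    spans$sac <- cbind(spec$saccades$onset_ms, spec$saccades$onset_ms + dur)
  }
  if (nrow(spec$blinks)) {
    pad <- 6 * dt # blink gap plus flanking spike samples
    spans$blink <- cbind(spec$blinks$start_ms - pad,
                         spec$blinks$start_ms + spec$blinks$duration_ms + pad)
  }
  if (nrow(spec$pursuits)) {
    spans$pur <- cbind(spec$pursuits$start_ms,
                       spec$pursuits$start_ms + spec$pursuits$duration_ms)
  }
  allsp <- do.call(rbind, spans)
  if (!is.null(allsp) && nrow(allsp) > 1L) {
    o <- order(allsp[, 1])
    allsp <- allsp[o, , drop = FALSE]
    if (any(allsp[-1, 1] < allsp[-nrow(allsp), 2])) {
      stop_spec("session events overlap in time")
    }
  }
  if (!is.null(allsp) && nrow(allsp) &&
      (min(allsp[, 1]) < 0 || max(allsp[, 2]) > spec$duration_ms)) {
    stop_spec("session events extend outside the session")
  }
  spec
}

#' Generate a ground-truth-labelled synthetic gaze session
#'
#' Deterministic for a fixed spec (the spec's seed drives all randomness).
#' Fixations hold the current position (plus fixation jitter); saccades are
#' inserted with [make_saccade_trajectory()]; blinks become invalid-sample
#' gaps whose 5 flanking samples on each side carry 40-100 deg/s position
#' excursions (so blink-edge cleanup rules are exercised); pursuit segments
#' drift at constant velocity. Measurement noise is added everywhere.
#'
#' @param spec a [session_spec()].
#' @return A list with elements `trace` (a [gaze_trace()]) and `truth`, a
#'   list of tibbles `saccades` (onset/offset/magnitude/direction/p1/p2/p3/
#'   bow and true start/end positions), `blinks` and `pursuits`.
#' @export
make_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  dt <- 1000 / spec$sampling_rate
  n <- floor(spec$duration_ms / dt)
  time_ms <- (seq_len(n) - 1) * dt
  x <- rep(spec$start_x, n)
  y <- rep(spec$start_y, n)
  fixating <- rep(TRUE, n)
  idx_of <- function(t_ms) as.integer(floor(t_ms / dt + 1e-9)) + 1L

  events <- bind_rows(
    if (nrow(spec$saccades)) mutate(spec$saccades, .kind = "saccade"),
    if (nrow(spec$pursuits)) mutate(
      tibble(
        onset_ms = spec$pursuits$start_ms,
        pursuit_duration = spec$pursuits$duration_ms,
        velocity = spec$pursuits$velocity,
        direction = spec$pursuits$direction
      ),
      .kind = "pursuit"
    )
  )
  truth_sac <- list()
  with_seed(spec$seed, {
    if (!is.null(events) && nrow(events)) {
      events <- arrange(events, .data$onset_ms)
      cur <- c(spec$start_x, spec$start_y)
      last_end <- 1L
      for (i in seq_len(nrow(events))) {
        ev <- events[i, ]
        i0 <- idx_of(ev$onset_ms)
        # fixation up to the event start holds the current position
        if (i0 > last_end) {
          x[last_end:(i0 - 1L)] <- cur[1]
          y[last_end:(i0 - 1L)] <- cur[2]
        }
        if (ev$.kind == "saccade") {
          traj <- make_saccade_trajectory(
            ev$magnitude, ev$direction, ev$p2, ev$p3, ev$bow_amplitude,
            start_x = cur[1], start_y = cur[2], rate = spec$sampling_rate
          )
          i1 <- min(i0 + nrow(traj) - 1L, n)
          keep <- seq_len(i1 - i0 + 1L)
          x[i0:i1] <- traj$x[keep]
          y[i0:i1] <- traj$y[keep]
          fixating[i0:i1] <- FALSE
          truth_sac[[length(truth_sac) + 1L]] <- tibble(
            onset_ms = time_ms[i0], offset_ms = time_ms[i1],
            magnitude = ev$magnitude, direction = wrap_angle(ev$direction),
            p1 = ev$magnitude, p2 = ev$p2, p3 = ev$p3,
            bow_amplitude = ev$bow_amplitude,
            start_x = cur[1], start_y = cur[2],
            end_x = traj$x[nrow(traj)], end_y = traj$y[nrow(traj)]
          )
          cur <- c(traj$x[nrow(traj)], traj$y[nrow(traj)])
          last_end <- i1 + 1L
        } else {
          i1 <- min(idx_of(ev$onset_ms + ev$pursuit_duration), n)
          th <- ev$direction * pi / 180
          tt <- time_ms[i0:i1] - time_ms[i0]
          v <- ev$velocity / 1000 # deg/ms
          x[i0:i1] <- cur[1] + v * tt * cos(th)
          y[i0:i1] <- cur[2] + v * tt * sin(th)
          fixating[i0:i1] <- FALSE
          cur <- c(x[i1], y[i1])
          last_end <- i1 + 1L
        }
      }
      if (last_end <= n) {
        x[last_end:n] <- cur[1]
        y[last_end:n] <- cur[2]
      }
    }

    if (spec$fixation_noise_sd > 0) {
      nf <- sum(fixating)
      x[fixating] <- x[fixating] + rnorm(nf, 0, spec$fixation_noise_sd)
      y[fixating] <- y[fixating] + rnorm(nf, 0, spec$fixation_noise_sd)
    }

    valid <- rep(TRUE, n)
    if (nrow(spec$blinks)) {
      for (i in seq_len(nrow(spec$blinks))) {
        b0 <- idx_of(spec$blinks$start_ms[i])
        b1 <- min(idx_of(spec$blinks$start_ms[i] + spec$blinks$duration_ms[i]) - 1L, n)
        valid[b0:b1] <- FALSE
        x[b0:b1] <- x[max(b0 - 1L, 1L)]
        y[b0:b1] <- y[max(b0 - 1L, 1L)]
        for (side in c(-1L, 1L)) {
          edge <- if (side < 0) b0 - 1L else b1 + 1L
          ks <- edge + side * (0:4)
          ks <- ks[ks >= 1L & ks <= n]
          if (!length(ks)) next
          phi <- runif(1, 0, 2 * pi)
          steps <- runif(5, 40, 100) * dt / 1000 # deg per sample
          offs <- rev(cumsum(steps))[seq_along(ks)] # largest at the gap edge
          x[ks] <- x[ks] + offs * cos(phi)
          y[ks] <- y[ks] + offs * sin(phi)
        }
      }
    }

    if (spec$noise_sd > 0) {
      x <- x + rnorm(n, 0, spec$noise_sd)
      y <- y + rnorm(n, 0, spec$noise_sd)
    }
  })

  truth <- list(
    saccades = if (length(truth_sac)) list_rbind(truth_sac) else tibble(
      onset_ms = double(), offset_ms = double(), magnitude = double(),
      direction = double(), p1 = double(), p2 = double(), p3 = double(),
      bow_amplitude = double(), start_x = double(), start_y = double(),
      end_x = double(), end_y = double()
    ),
    blinks = spec$blinks, pursuits = spec$pursuits
  )
  list(
    trace = gaze_trace(time_ms, x, y, valid,
      trace_id = paste0("synthetic-seed", spec$seed)
    ),
    truth = truth
  )
}

#' Draw a randomized, realistic session spec
#'
#' Emulates 1 kHz natural-viewing recordings: saccade magnitudes are
#' log-uniform on 2-20 degrees; durations follow a main-sequence-like
#' rule (2.2 ms/deg + 21 ms, jittered, clipped to 18-95 ms) from which the
#' model time scale `p2` is derived; shape `p3` is uniform on 1.5-2.5;
#' directions are uniform, resampled so gaze stays within a 33 x 19 degree
#' viewing area; inter-saccade fixations last 250-450 ms. Blinks
#' (~120 ms) and low-velocity pursuit segments (10 deg/s, 300 ms) are
#' interleaved into fixations.
#'
#' @param n_saccades number of saccades.
#' @param seed integer seed (drives both the spec draw and the session).
#' @param noise_sd measurement noise sd, degrees.
#' @param fixation_noise_sd fixation jitter sd, degrees.
#' @param n_blinks,n_pursuits number of blink/pursuit events.
#' @param bow_range absolute bow amplitudes are drawn uniform on this range
#'   (sign random), degrees.
#' @return A [session_spec()].
#' @export
random_session_spec <- function(n_saccades = 100, seed = 1L,
                                noise_sd = 0.02, fixation_noise_sd = 0.01,
                                n_blinks = 5, n_pursuits = 3,
                                bow_range = c(0, 0.3)) {
  half_w <- 16.5
  half_h <- 9.5
  with_seed(seed, {
    blink_every <- if (n_blinks > 0) max(1L, floor(n_saccades / n_blinks)) else Inf
    pursuit_every <- if (n_pursuits > 0) max(1L, floor(n_saccades / n_pursuits)) else Inf
    cursor <- 200
    pos <- c(0, 0)
    sac <- vector("list", n_saccades)
    blinks <- list()
    pursuits <- list()
    for (i in seq_len(n_saccades)) {
      fix <- runif(1, 250, 450)
      if (is.finite(blink_every) && i %% blink_every == 0 && length(blinks) < n_blinks) {
        bdur <- runif(1, 80, 150)
        blinks[[length(blinks) + 1L]] <- tibble(start_ms = cursor + 30, duration_ms = bdur)
        cursor <- cursor + 30 + bdur + 30
      } else if (is.finite(pursuit_every) && i %% pursuit_every == 0 &&
                 length(pursuits) < n_pursuits) {
        pdir <- wrap_angle(atan2(-pos[2], -pos[1]) * 180 / pi + runif(1, -30, 30))
        pursuits[[length(pursuits) + 1L]] <- tibble(
          start_ms = cursor + 10, duration_ms = 300, velocity = 10, direction = pdir
        )
        pos <- pos + 3 * c(cos(pdir * pi / 180), sin(pdir * pi / 180))
        cursor <- cursor + 10 + 300 + 10
      }
      mag <- exp(runif(1, log(2), log(20)))
      p3 <- runif(1, 1.5, 2.5)
      dur <- min(max(2.2 * mag + 21 + rnorm(1, 0, 3), 18), 95)
      # resample direction until the landing point stays on screen
      repeat {
        dir <- runif(1, 0, 360)
        land <- pos + mag * c(cos(dir * pi / 180), sin(dir * pi / 180))
        if (abs(land[1]) <= half_w && abs(land[2]) <= half_h) break
      }
      bow <- sample(c(-1, 1), 1) * runif(1, bow_range[1], bow_range[2])
      onset <- round(cursor + fix) # align onsets to the 1 kHz sampling grid
      sac[[i]] <- tibble(
        onset_ms = onset, magnitude = mag, direction = dir,
        p2 = p2_for_duration(dur, p3), p3 = p3, bow_amplitude = bow
      )
      pos <- land
      cursor <- onset + saccade_model_duration(sac[[i]]$p2, p3) + 5
    }
    session_spec(
      duration_ms = cursor + 400, sampling_rate = 1000,
      saccades = list_rbind(sac),
      blinks = if (length(blinks)) list_rbind(blinks) else NULL,
      pursuits = if (length(pursuits)) list_rbind(pursuits) else NULL,
      fixation_noise_sd = fixation_noise_sd, noise_sd = noise_sd,
      seed = seed
    )
  })
}
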