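test_that("blink excision removes fast flanking samples and nothing else", {
  # clean trace below threshold everywhere is untouched
  tr <- gaze_trace(0:99, x = seq(0, 0.5, length.out = 100), y = 0)
  expect_equal(excise_blinks(tr)$valid, rep(TRUE, 100))

  # synthetic blink with ~60 deg/s flanking spikes
  n <- 200
  x <- rep(1, n)
  valid <- rep(TRUE, n)
  valid[91:110] <- FALSE
  spike <- cumsum(rep(0.06, 5)) # 60 deg/s steps
  x[86:90] <- 1 + rev(spike) * -1 + max(spike) # ramp up toward the gap
  x[86:90] <- 1 + cumsum(rep(0.06, 5))
  x[111:115] <- 1 + rev(cumsum(rep(0.06, 5)))
  tr <- gaze_trace(seq_len(n) - 1, x, 0, valid)
  out <- excise_blinks(tr)
  expect_true(all(!out$valid[86:115]))
  expect_true(all(out$valid[1:85]))
  expect_true(all(out$valid[116:n]))

  # gap at the trace start: only the trailing edge is processed, no error
  valid2 <- rep(TRUE, 50)
  valid2[1:10] <- FALSE
  tr2 <- gaze_trace(0:49, 0, 0, valid2)
  expect_equal(sum(!excise_blinks(tr2)$valid), 10)

  all_bad <- gaze_trace(0:9, 0, 0, valid = FALSE)
  expect_error(excise_blinks(all_bad), class = "saccurv_error_insufficient_data")
})

test_that("gap interpolation uses natural cubic splines and edge holds", {
  # no gaps -> identity
  tr <- gaze_trace(0:49, x = rnorm(50), y = rnorm(50))
  out <- interpolate_gaps(tr)
  expect_equal(out$x, tr$x)
  expect_false(any(out$interpolated))

  # linear ramp with an interior gap is filled on the line
  x <- seq(0, 9.9, by = 0.1)
  valid <- rep(TRUE, 100)
  valid[40:49] <- FALSE
  tr <- gaze_trace(0:99, x, 0, valid)
  out <- interpolate_gaps(tr)
  expect_equal(out$x[40:49], x[40:49], tolerance = 1e-6)
  expect_true(all(out$valid))
  expect_equal(which(out$interpolated), 40:49)

  # sinusoid with a 20 ms gap matches an independent spline evaluation
  t <- 0:199
  xs <- sin(2 * pi * t / 80)
  valid <- rep(TRUE, 200)
  valid[100:119] <- FALSE
  tr <- gaze_trace(t, xs, 0, valid)
  out <- interpolate_gaps(tr)
  ref <- spline(x = t[valid], y = xs[valid], xout = t[100:119], method = "natural")$y
  expect_equal(out$x[100:119], ref, tolerance = 1e-12)

  # edge gap: nearest-valid hold
  valid2 <- rep(TRUE, 50)
  valid2[1:5] <- FALSE
  tr2 <- gaze_trace(0:49, seq(1, 5.9, by = 0.1), 0, valid2)
  out2 <- interpolate_gaps(tr2)
  expect_equal(out2$x[1:5], rep(tr2$x[6], 5))

  few <- gaze_trace(0:9, 0, 0, valid = c(TRUE, TRUE, TRUE, rep(FALSE, 7)))
  expect_error(interpolate_gaps(few), class = "saccurv_error_insufficient_data")
})

test_that("Savitzky-Golay smoothing preserves cubics and reduces noise", {
  t <- 0:99
  cubic <- 1 + 0.02 * t - 3e-4 * t^2 + 2e-6 * t^3
  tr <- gaze_trace(t, cubic, -cubic)
  out <- smooth_gaze(tr)
  expect_equal(out$x, cubic, tolerance = 1e-9)
  expect_equal(out$y, -cubic, tolerance = 1e-9)

  const <- smooth_gaze(gaze_trace(t, 2, 3))
  expect_equal(const$x, rep(2, 100), tolerance = 1e-12)

  # noisy saccade: residual-to-truth variance shrinks
  traj <- make_saccade_trajectory(5, 0, p2 = 12, p3 = 2)
  truth <- c(rep(0, 50), traj$x, rep(tail(traj$x, 1), 50))
  set.seed(8)
  noisy <- truth + rnorm(length(truth), 0, 0.02)
  sm <- smooth_gaze(gaze_trace(seq_along(truth) - 1, noisy, 0))
  expect_lt(var(sm$x - truth), var(noisy - truth))

  expect_error(smooth_gaze(gaze_trace(0:9, 0, 0)),
               class = "saccurv_error_insufficient_data")
})

test_that("speed is the norm of the central-difference velocity", {
  t <- 0:99
  expect_equal(compute_speed(gaze_trace(t, 4, -2))$speed, rep(0, 100))

  # linear motion at 0.1 deg/ms
  sp <- compute_speed(gaze_trace(t, 0.1 * t, 5))$speed
  expect_equal(sp[2:99], rep(0.1, 98), tolerance = 1e-12)

  # interior speeds of a model trajectory match the analytic velocity to 1%
  traj <- make_saccade_trajectory(5, 0, p2 = 10, p3 = 2)
  sp2 <- compute_speed(gaze_trace(traj$t_ms, traj$x, traj$y))$speed
  ref <- saccade_velocity(traj$t_ms, 5, 10, 2)
  i <- 3:(length(ref) - 2)
  expect_lt(max(abs(sp2[i] - ref[i])) / max(ref), 0.01)
})

test_that("speed is translation invariant and scale equivariant", {
  ses <- clean_session(n = 5, seed = 13)
  base <- preprocess_gaze(ses$trace)
  shifted <- ses$trace
  shifted$x <- shifted$x + 7
  shifted$y <- shifted$y - 3
  sp_shift <- preprocess_gaze(rebuild <- gaze_trace(shifted$time_ms, shifted$x, shifted$y, shifted$valid))
  expect_equal(sp_shift$speed, base$speed, tolerance = 1e-10)

  scaled <- gaze_trace(ses$trace$time_ms, 2 * ses$trace$x, 2 * ses$trace$y, ses$trace$valid)
  sp_scaled <- preprocess_gaze(scaled)
  expect_equal(sp_scaled$speed, 2 * base$speed, tolerance = 1e-10)
})

test_that("preprocessing alters true peak speed only within filter physics", {
  # the 15-sample cubic filter is nearly transparent for longer saccades
  # (duration >= 40 ms): peak speed changes by <2%. Short saccades whose
  # velocity peak is barely wider than the window are attenuated more
  # (up to ~29% at 16 ms with a cusp-like p3 = 1.5 profile) but the
  # attenuation stays bounded below 30% over the generator's full range
  errs <- sapply(list(c(8, 40, 2), c(15, 55, 1.8), c(20, 65, 2.5)), function(p) {
    p2 <- p2_for_duration(p[2], p[3])
    traj <- make_saccade_trajectory(p[1], 0, p2 = p2, p3 = p[3])
    pad <- 100
    x <- c(rep(0, pad), traj$x, rep(tail(traj$x, 1), pad))
    tr <- gaze_trace(seq_along(x) - 1, x, 0)
    pre <- compute_speed(smooth_gaze(tr))
    tfine <- seq(0.01, max(traj$t_ms), by = 0.01)
    truepk <- max(saccade_velocity(tfine, p[1], p2, p[3]))
    abs(max(pre$speed) / truepk - 1)
  })
  expect_true(all(errs < 0.02))

  short <- sapply(list(c(2, 16, 1.5), c(2, 20, 1.5), c(3, 25, 2)), function(p) {
    p2 <- p2_for_duration(p[2], p[3])
    traj <- make_saccade_trajectory(p[1], 0, p2 = p2, p3 = p[3])
    x <- c(rep(0, 100), traj$x, rep(tail(traj$x, 1), 100))
    tr <- gaze_trace(seq_along(x) - 1, x, 0)
    pre <- compute_speed(smooth_gaze(tr))
    tfine <- seq(0.01, max(traj$t_ms), by = 0.01)
    abs(max(pre$speed) / max(saccade_velocity(tfine, p[1], p2, p[3])) - 1)
  })
  expect_true(all(short < 0.30))
})
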