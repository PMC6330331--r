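test_that("curvature is zero on straight lines and matches the brute-force oracle", {
  straight <- tibble::tibble(x = seq(0, 29), y = rep(0, 30))
  expect_identical(pointwise_curvature(straight)$k, 0)
  expect_identical(pointwise_curvature(straight, "perpendicular")$k, 0)

  # quarter circle of radius 2 at 30 equal angular steps
  th <- seq(0, pi / 2, length.out = 30)
  arc <- tibble::tibble(x = 2 * cos(th), y = 2 * sin(th))
  for (variant in c("as_written", "perpendicular")) {
    got <- pointwise_curvature(arc, variant)
    if (variant == "as_written") {
      ref <- oracle_curvature(arc$x, arc$y)
      expect_equal(got$pointwise, ref$pointwise, tolerance = 1e-12)
      expect_equal(got$k, ref$k, tolerance = 1e-12)
    }
    expect_true(all(got$pointwise >= 0))
    # k is the median of the pointwise series (independent sort-based median)
    s <- sort(got$pointwise)
    n <- length(s)
    med <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_identical(got$k, med)
  }

  # a straight path traversed at varying speed: as_written sees tangential
  # acceleration, the perpendicular variant does not
  vary <- tibble::tibble(x = c(0, 1, 3, 6, 10, 15), y = 0)
  expect_gt(pointwise_curvature(vary)$k, 0)
  expect_identical(pointwise_curvature(vary, "perpendicular")$k, 0)

  expect_error(pointwise_curvature(tibble::tibble(x = 1:3, y = 0)),
               class = "saccurv_error_insufficient_data")
  expect_error(pointwise_curvature(tibble::tibble(x = rep(1, 6), y = rep(2, 6))),
               class = "saccurv_error_degenerate")
})

test_that("curvature is invariant under rotation, translation and scaling", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    path <- tibble::tibble(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    for (variant in c("as_written", "perpendicular")) {
      k0 <- pointwise_curvature(path, variant)$k
      th <- runif(1, 0, 2 * pi)
      sc <- exp(runif(1, -2, 2))
      dx <- runif(1, -50, 50)
      dy <- runif(1, -50, 50)
      moved <- tibble::tibble(
        x = sc * (path$x * cos(th) - path$y * sin(th)) + dx,
        y = sc * (path$x * sin(th) + path$y * cos(th)) + dy
      )
      expect_equal(pointwise_curvature(moved, variant)$k, k0, tolerance = 1e-10)
    }
  }
})

test_that("measured curvature increases strictly with injected bow amplitude", {
  bows <- seq(0, 0.9, by = 0.1)
  traj_of <- function(b) make_saccade_trajectory(5, direction = 30, p2 = 10, p3 = 2,
                                                 bow_amplitude = b)
  # the perpendicular variant isolates path bending: strictly monotone
  kp <- sapply(bows, function(b) pointwise_curvature(traj_of(b), "perpendicular")$k)
  expect_true(all(diff(kp) > 0))
  expect_equal(cor(bows, kp, method = "spearman"), 1)
  # the as-written variant carries a tangential-acceleration floor that
  # dominates the median at extreme bows; it is monotone through 0.8 deg
  ka <- sapply(bows, function(b) pointwise_curvature(traj_of(b))$k)
  expect_true(all(diff(ka[1:9]) > 0))
  expect_gte(cor(bows, ka, method = "spearman"), 0.95)
})

test_that("profile fit recovers model parameters and reduces to the standard exponential", {
  # self-consistency on the model's own output
  traj <- make_saccade_trajectory(5, 20, p2 = 10, p3 = 2)
  tr <- compute_speed(gaze_trace(traj$t_ms, traj$x, traj$y))
  ev <- tibble::tibble(onset_ms = 0, offset_ms = max(traj$t_ms))
  fit <- fit_velocity_profile(ev, tr)
  expect_equal(fit$p1, 5, tolerance = 0.01)
  expect_equal(fit$p2, 10, tolerance = 0.01)
  expect_equal(fit$p3, 2, tolerance = 0.01)
  expect_lt(fit$deviation, 1e-4)
  expect_true(fit$converged)

  # standard exponential saturation: fitted p3 converges to 1
  t <- 0:60
  d <- 5 * (1 - exp(-t / 10))
  tr2 <- compute_speed(gaze_trace(t, d, 0))
  fit2 <- fit_velocity_profile(tibble::tibble(onset_ms = 0, offset_ms = 60), tr2)
  expect_equal(fit2$p3, 1, tolerance = 1e-3)

  expect_error(
    fit_velocity_profile(tibble::tibble(onset_ms = 0, offset_ms = 5), tr2),
    class = "saccurv_error_insufficient_data"
  )
})

test_that("deviation matches an independent grid + polish re-implementation", {
  set.seed(5)
  traj <- make_saccade_trajectory(6, 0, p2 = 12, p3 = 1.9)
  x <- c(rep(0, 30), traj$x + rnorm(nrow(traj), 0, 0.02), rep(tail(traj$x, 1), 30))
  tr <- compute_speed(gaze_trace(seq_along(x) - 1, x, 0))
  i0 <- 31
  i1 <- 30 + nrow(traj)
  ev <- tibble::tibble(onset_ms = tr$time_ms[i0], offset_ms = tr$time_ms[i1])
  fit <- fit_velocity_profile(ev, tr)
  d <- sqrt((tr$x[i0:i1] - tr$x[i0])^2 + (tr$y[i0:i1] - tr$y[i0])^2)
  ref <- oracle_profile_fit(
    t = tr$time_ms[i0:i1] - tr$time_ms[i0], d = d, speed = tr$speed[i0:i1]
  )
  expect_equal(fit$deviation, ref$deviation, tolerance = 0.02)
})

test_that("deviation is nonnegative and zero only for model-consistent speeds", {
  traj <- make_saccade_trajectory(5, 0, p2 = 10, p3 = 2)
  tr <- compute_speed(gaze_trace(traj$t_ms, traj$x, traj$y))
  ev <- tibble::tibble(onset_ms = 0, offset_ms = max(traj$t_ms))
  base <- fit_velocity_profile(ev, tr)
  expect_gte(base$deviation, 0)
  expect_lt(base$deviation, 1e-10)

  # perturb the measured speed at one sample: deviation must become positive
  tr2 <- tr
  tr2$speed[10] <- tr2$speed[10] + 0.05
  fit2 <- fit_velocity_profile(ev, tr2)
  expect_gt(fit2$deviation, 1e-3)
})

test_that("profile fit depends only on displacement, not start point or direction", {
  fits <- lapply(list(c(0, 0, 45), c(5, -3, 220)), function(s) {
    traj <- make_saccade_trajectory(7, s[3], p2 = 14, p3 = 2.2,
                                    start_x = s[1], start_y = s[2])
    tr <- compute_speed(gaze_trace(traj$t_ms, traj$x, traj$y))
    fit_velocity_profile(tibble::tibble(onset_ms = 0, offset_ms = max(traj$t_ms)), tr)
  })
  expect_equal(fits[[1]]$p1, fits[[2]]$p1, tolerance = 1e-8)
  expect_equal(fits[[1]]$p3, fits[[2]]$p3, tolerance = 1e-8)
  expect_equal(fits[[1]]$deviation, fits[[2]]$deviation, tolerance = 1e-10)
})

test_that("add_saccade_metrics fills metric columns for accepted events only", {
  ses <- clean_session(n = 6, seed = 31)
  pre <- preprocess_gaze(ses$trace)
  ev <- add_saccade_metrics(detect_saccades(pre), pre)
  acc <- ev[ev$accepted, ]
  expect_true(all(is.finite(acc$curvature)))
  expect_true(all(is.finite(acc$deviation)))
  expect_true(all(acc$p1 > 0 & acc$p3 >= 0.5))
  rej <- ev[!ev$accepted, ]
  if (nrow(rej)) expect_true(all(is.na(rej$curvature)))
})
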