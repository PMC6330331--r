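make_pulse_trace <- function(pulse_speed = 0.1, pulse_len = 12, n = 200) {
  # literal rectangular speed pulse injected directly (positions consistent)
  x <- numeric(n)
  x[100:(100 + pulse_len - 1)] <- cumsum(rep(pulse_speed, pulse_len))
  x[(100 + pulse_len):n] <- x[100 + pulse_len - 1]
  out <- gaze_trace(seq_len(n) - 1, x, 0)
  sp <- rep(0.001, n)
  sp[100:(100 + pulse_len - 1)] <- pulse_speed
  out$speed <- sp
  out
}

test_that("segmentation finds maximal suprathreshold runs", {
  quiet <- gaze_trace(0:99, 0, 0)
  quiet$speed <- rep(0.01, 100)
  expect_equal(nrow(segment_saccades(quiet)), 0)

  tr <- make_pulse_trace(pulse_speed = 0.1, pulse_len = 12)
  ev <- segment_saccades(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_ms, 12)

  # a 9 ms pulse fails the 10 ms sustain rule
  short <- make_pulse_trace(pulse_len = 9)
  expect_equal(nrow(segment_saccades(short)), 0)
})

test_that("detection on a clean synthetic session recovers every saccade", {
  ses <- clean_session(n = 20, seed = 42)
  pre <- preprocess_gaze(ses$trace)
  ev <- detect_saccades(pre)
  acc <- ev[ev$accepted, ]
  truth <- ses$truth$saccades
  m <- match_saccades(truth, acc)
  expect_equal(sum(!is.na(m)), nrow(truth)) # recall 1
  onset_err <- abs(acc$onset_ms[m] - truth$onset_ms)
  expect_lte(max(onset_err), 3)
  # magnitudes agree with truth (thresholded segment slightly clips the tails)
  expect_lt(max(abs(acc$magnitude[m] - truth$magnitude) / truth$magnitude), 0.06)
})

test_that("inclusion rules reject with the first failing reason", {
  ses <- clean_session(n = 10, seed = 21)
  pre <- preprocess_gaze(ses$trace)
  cand <- segment_saccades(pre)
  cfg <- run_config()

  # every candidate lands in exactly one of accepted / rejected
  out <- apply_saccade_filters(cand, pre, cfg)
  expect_equal(sum(out$accepted) + sum(!is.na(out$rejection_reason)), nrow(out))
  expect_true(all(is.na(out$rejection_reason[out$accepted])))

  # magnitude rule: shrink a candidate's magnitude below 1 degree
  fake <- cand[1, ]
  fake$magnitude <- 0.5
  expect_equal(apply_saccade_filters(fake, pre, cfg)$rejection_reason, "magnitude_low")
  fake$magnitude <- 45
  expect_equal(apply_saccade_filters(fake, pre, cfg)$rejection_reason, "magnitude_high")
  fake$magnitude <- 5
  fake$duration_ms <- 15
  expect_equal(apply_saccade_filters(fake, pre, cfg)$rejection_reason, "duration_short")

  # quartile rule: a slow uniform initial phase before a late fast peak
  # (a pursuit-like lead-in) makes first-quartile speed < 0.15 x peak
  n <- 300
  sp <- rep(0.001, n)
  sp[101:160] <- 0.04                      # slow phase
  sp[161:175] <- 0.4                       # late peak
  sp[176:180] <- c(0.2, 0.1, 0.06, 0.05, 0.04) # decay below terminal limit
  x <- cumsum(sp)
  tr <- gaze_trace(seq_len(n) - 1, x, 0)
  tr$speed <- sp
  cand2 <- segment_saccades(tr)
  out2 <- apply_saccade_filters(cand2, tr, cfg)
  expect_false(any(out2$accepted))
  expect_equal(out2$rejection_reason, "slow_first_quartile")

  # model-generated 5-degree saccade passes every rule
  ses5 <- make_session(session_spec(
    duration_ms = 800,
    saccades = tibble::tibble(
      onset_ms = 300, magnitude = 5, direction = 0,
      p2 = 10, p3 = 2, bow_amplitude = 0
    )
  ))
  pre5 <- preprocess_gaze(ses5$trace)
  ev5 <- detect_saccades(pre5)
  expect_equal(sum(ev5$accepted), 1)
})

test_that("candidates touching the trace boundary are rejected", {
  traj <- make_saccade_trajectory(5, 0, p2 = 10, p3 = 2)
  x <- c(traj$x, rep(tail(traj$x, 1), 100))
  tr <- compute_speed(smooth_gaze(gaze_trace(seq_along(x) - 1, x, 0)))
  ev <- detect_saccades(tr)
  expect_true(all(ev$rejection_reason[ev$onset_idx == 1] == "boundary"))
})

test_that("orientation taxonomy follows the 5 and 22 degree bands", {
  cases <- tibble::tribble(
    ~dir, ~orient, ~left, ~down,
    0, "horizontal", FALSE, FALSE,
    3, "horizontal", FALSE, FALSE,
    5, "horizontal", FALSE, FALSE,
    6, "oblique", FALSE, FALSE,
    45, "oblique", FALSE, FALSE,
    68, "vertical", FALSE, FALSE,
    85, "vertical", FALSE, FALSE,
    90, "vertical", FALSE, FALSE,
    112, "vertical", TRUE, FALSE,
    113, "oblique", TRUE, FALSE,
    175, "horizontal", TRUE, FALSE,
    180, "horizontal", TRUE, FALSE,
    185, "horizontal", TRUE, TRUE,
    200, "oblique", TRUE, TRUE,
    248, "vertical", TRUE, TRUE,
    270, "vertical", FALSE, TRUE,
    292, "vertical", FALSE, TRUE,
    359, "horizontal", FALSE, TRUE
  )
  got <- classify_orientation(cases$dir)
  expect_equal(got$orientation, cases$orient)
  expect_equal(got$leftward, cases$left)
  expect_equal(got$downward, cases$down)
})

test_that("detection meets recall/precision targets under measurement noise", {
  ses <- make_session(random_session_spec(n_saccades = 100, seed = 1, noise_sd = 0.02))
  pre <- preprocess_gaze(ses$trace)
  ev <- detect_saccades(pre)
  acc <- ev[ev$accepted, ]
  truth <- ses$truth$saccades
  m <- match_saccades(truth, acc)
  recall <- mean(!is.na(m))
  precision <- sum(!is.na(m)) / nrow(acc)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  expect_lte(median(abs(acc$onset_ms[m[!is.na(m)]] - truth$onset_ms[!is.na(m)])), 3)
})

test_that("main sequence is monotone and the log-log fit matches an OLS oracle", {
  specs <- tibble::tibble(
    onset_ms = seq(300, by = 600, length.out = 3),
    magnitude = c(2, 4, 8), direction = c(0, 90, 180),
    p2 = 12, p3 = 2, bow_amplitude = 0
  )
  ses <- make_session(session_spec(duration_ms = 2400, saccades = specs))
  pre <- preprocess_gaze(ses$trace)
  ev <- detect_saccades(pre)
  acc <- ev[ev$accepted, ]
  acc <- acc[order(acc$magnitude), ]
  expect_true(all(diff(acc$peak_velocity) > 0))

  ses2 <- make_session(random_session_spec(n_saccades = 100, seed = 77, noise_sd = 0.01))
  pre2 <- preprocess_gaze(ses2$trace)
  ev2 <- detect_saccades(pre2)
  ms <- main_sequence(ev2)
  X <- cbind(1, log10(ms$data$magnitude))
  ref <- oracle_ols(X, log10(ms$data$peak_velocity))
  expect_equal(unname(coef(ms$fit)), ref, tolerance = 1e-10)
  expect_lt(abs(coef(ms$fit)[2] - ref[2]), 0.1)

  one_mag <- ev2[ev2$accepted, ][1:5, ]
  one_mag$magnitude <- 4
  expect_error(main_sequence(one_mag), class = "saccurv_error_spec")
  expect_error(main_sequence(ev2[0, ]), class = "saccurv_error_insufficient_data")
})
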