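# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package implementation.

# pointwise curvature: literal transcription. numerator = Euclidean norm of
# the second difference; denominator = total path length; k = median by sort.
oracle_curvature <- function(x, y) {
  T_ <- length(x)
  denom <- 0
  for (t in 2:T_) {
    denom <- denom + sqrt((x[t] - x[t - 1])^2 + (y[t] - y[t - 1])^2)
  }
  kt <- numeric(0)
  for (t in 2:(T_ - 1)) {
    num <- sqrt((x[t + 1] - 2 * x[t] + x[t - 1])^2 +
                (y[t + 1] - 2 * y[t] + y[t - 1])^2)
    kt <- c(kt, num / denom)
  }
  s <- sort(kt)
  n <- length(s)
  k <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  list(pointwise = kt, k = k)
}

# ordinary least squares through the normal equations
oracle_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# compressed exponential position model, written out again
oracle_f <- function(t, p1, p2, p3) {
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    out[i] <- if (t[i] <= 0) 0 else p1 * (1 - exp(-(t[i] / p2)^p3))
  }
  out
}

# grid search + Nelder-Mead polish for the profile fit (position-domain SSE),
# then RMS velocity error with the model velocity discretized by the same
# central-difference stencil used on the data (interior samples assumed).
oracle_profile_fit <- function(t, d, speed, dt = 1) {
  sse <- function(p) {
    if (any(p <= 0) || p[3] < 0.5 || p[3] > 10) return(Inf)
    sum((d - oracle_f(t, p[1], p[2], p[3]))^2)
  }
  mag <- d[length(d)]
  dur <- t[length(t)]
  best <- NULL
  best_v <- Inf
  for (p1 in mag * c(0.9, 1.0, 1.1)) {
    for (p2 in dur * c(0.2, 0.35, 0.5)) {
      for (p3 in c(1, 1.5, 2, 2.5, 3)) {
        v <- sse(c(p1, p2, p3))
        if (v < best_v) {
          best_v <- v
          best <- c(p1, p2, p3)
        }
      }
    }
  }
  opt <- optim(best, sse, control = list(maxit = 5000, reltol = 1e-14))
  p <- opt$par
  # discrete model velocity (central; one-sided at the two ends of the event
  # window only if the window touches the trace boundary -- the caller passes
  # interior events, so use central with f(t<0)=0 and forward at sample 1
  # when t[1] == 0 and there is no sample before it in the trace)
  mvel <- numeric(length(t))
  for (i in seq_along(t)) {
    mvel[i] <- (oracle_f(t[i] + dt, p[1], p[2], p[3]) -
                oracle_f(t[i] - dt, p[1], p[2], p[3])) / (2 * dt)
  }
  list(par = p, deviation = sqrt(mean((speed - mvel)^2)))
}

# frame-difference metric, pixel by pixel
oracle_frame_metric <- function(frames, eps = 1e-6) {
  out <- numeric(length(frames) - 1)
  for (i in seq_len(length(frames) - 1)) {
    a <- frames[[i]]
    b <- frames[[i + 1]]
    acc <- 0
    for (r in seq_len(nrow(a))) {
      for (c in seq_len(ncol(a))) {
        acc <- acc + abs(b[r, c] - a[r, c])
      }
    }
    out[i] <- log(eps + acc / (nrow(a) * ncol(a)))
  }
  out
}

# match detected events to ground-truth saccades by interval overlap;
# returns one row per truth saccade with the matched event index (or NA)
match_saccades <- function(truth, events) {
  idx <- integer(nrow(truth))
  used <- logical(nrow(events))
  for (i in seq_len(nrow(truth))) {
    j <- which(!used &
               events$onset_ms <= truth$offset_ms[i] &
               events$offset_ms >= truth$onset_ms[i])
    if (length(j)) {
      used[j[1]] <- TRUE
      idx[i] <- j[1]
    } else {
      idx[i] <- NA_integer_
    }
  }
  idx
}

# a small clean session used by several files
clean_session <- function(n = 10, seed = 7, noise_sd = 0, ...) {
  make_session(random_session_spec(
    n_saccades = n, seed = seed, noise_sd = noise_sd,
    fixation_noise_sd = 0, n_blinks = 0, n_pursuits = 0, ...
  ))
}
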