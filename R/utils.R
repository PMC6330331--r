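# internal helpers shared across modules

# central differences with one-sided endpoints; x per-sample, dt in ms.
# returns derivative in units of x per ms.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) abort("need at least 2 samples to differentiate", class = "saccurv_error_insufficient_data")
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d
}

# wrap an angle in degrees into [0, 360)
wrap_angle <- function(a) ((a %% 360) + 360) %% 360

# smallest absolute angular distance between two directions in degrees
angle_dist <- function(a, b) {
  d <- abs(wrap_angle(a) - wrap_angle(b))
  pmin(d, 360 - d)
}

# contiguous runs of TRUE in a logical vector -> tibble(start, end) indices
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

stop_insufficient <- function(msg) {
  abort(msg, class = "saccurv_error_insufficient_data")
}

stop_format <- function(msg) {
  abort(msg, class = "saccurv_error_format")
}

stop_spec <- function(msg) {
  abort(msg, class = "saccurv_error_spec")
}

# seed guard: run code with a temporary RNG state derived from `seed`,
# restoring the caller's state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
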