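#' The compressed exponential saccade model
#'
#' Along-track displacement of a saccade is modelled as the generalized
#' (compressed) exponential saturation curve
#' \deqn{f(t) = p_1 \left[1 - \exp\left(-(t/p_2)^{p_3}\right)\right]}
#' where `p1` (degrees) is the saccade amplitude, `p2` (ms) rescales the
#' duration, and the dimensionless shape parameter `p3` controls the decay
#' trend: `p3 = 1` recovers the standard exponential saturation, while
#' `p3 > 1` gives the slower deceleration than acceleration phase typical
#' of real saccades. The model velocity is the time derivative
#' \deqn{f'(t) = \frac{p_1 p_3}{p_2}\,(t/p_2)^{p_3-1}
#'   \exp\left(-(t/p_2)^{p_3}\right).}
#'
#' `saccade_position()` and `saccade_velocity()` evaluate the two curves
#' (`t` in ms since saccade onset; both are 0 for `t < 0`, and the velocity
#' at `t = 0` takes its right limit). `saccade_model_duration()` gives the
#' operational duration, the time at which 99.9% of the amplitude is
#' reached; `p2_for_duration()` inverts it.
#'
#' @param t time since saccade onset, ms.
#' @param p1 amplitude, degrees.
#' @param p2 time scale, ms.
#' @param p3 shape parameter, dimensionless, > 0.
#' @return Position in degrees, velocity in deg/ms, or a duration/time
#'   scale in ms.
#' @export
#' @examples
#' saccade_position(c(0, 5, 10, 50), p1 = 5, p2 = 10, p3 = 2)
#' saccade_model_duration(p2 = 10, p3 = 2)
saccade_position <- function(t, p1, p2, p3) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- p1 * (1 - exp(-(t[pos] / p2)^p3))
  out
}

#' @rdname saccade_position
#' @export
saccade_velocity <- function(t, p1, p2, p3) {
  out <- numeric(length(t))
  pos <- t > 0
  u <- (t[pos] / p2)^p3
  out[pos] <- (p1 * p3 / p2) * (t[pos] / p2)^(p3 - 1) * exp(-u)
  at0 <- t == 0
  if (any(at0)) {
    out[at0] <- if (p3 > 1) 0 else if (p3 == 1) p1 / p2 else Inf
  }
  out
}

# truncation fraction: the model is asymptotic, so a saccade operationally
# ends when 99.9% of the amplitude has been covered
model_truncation <- 0.999

#' @rdname saccade_position
#' @export
saccade_model_duration <- function(p2, p3) {
  p2 * (-log(1 - model_truncation))^(1 / p3)
}

#' @rdname saccade_position
#' @param duration_ms target operational duration, ms.
#' @export
p2_for_duration <- function(duration_ms, p3) {
  duration_ms / (-log(1 - model_truncation))^(1 / p3)
}
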