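#' Generate a synthetic clip with abrupt cuts and gradual fades
#'
#' Frames are constant-intensity fields plus i.i.d. Gaussian pixel noise.
#' An abrupt cut at frame `f` switches the base level from that frame on
#' (the mean-intensity change at every cut must be at least 40 gray
#' levels); a fade interpolates the base level linearly over its span.
#' Frames are rounded to integers and clipped to \[0, 255\] so a
#' write/read round trip through [write_frames()] is exact.
#'
#' @param n_frames number of frames (>= 2).
#' @param cut_frames strictly increasing frame indices (1-based, in
#'   `2:n_frames`) at which a new scene starts.
#' @param fade_spans list of `c(start, len)` pairs: the base level ramps
#'   linearly from `levels` value in force at `start` to the next level
#'   over `len` frames.
#' @param base_levels mean intensities of the successive segments; length
#'   `length(cut_frames) + length(fade_spans) + 1`.
#' @param noise_sd pixel noise sd, gray levels.
#' @param width,height frame dimensions, pixels.
#' @param frame_rate frames per second.
#' @param seed integer seed.
#' @param clip_id label.
#' @return A list with elements `clip` (a [clip_frames()]) and `truth`
#'   (tibbles `cuts` and `fades`).
#' @export
#' @examples
#' out <- make_clip(30, cut_frames = c(10, 25),
#'                  base_levels = c(60, 120, 190), noise_sd = 2, seed = 1)
#' out$truth$cuts
make_clip <- function(n_frames, cut_frames = integer(), fade_spans = list(),
                      base_levels = NULL, noise_sd = 0,
                      width = 32, height = 32, frame_rate = 30,
                      seed = 1L, clip_id = "synthetic-clip") {
  if (n_frames < 2) stop_insufficient("a clip needs at least 2 frames")
  cut_frames <- as.integer(cut_frames)
  if (length(cut_frames)) {
    if (any(diff(cut_frames) <= 0)) stop_spec("cut frames must be strictly increasing")
    if (any(cut_frames < 2 | cut_frames > n_frames)) stop_spec("cut frames out of range")
  }
  n_seg <- length(cut_frames) + length(fade_spans) + 1L
  base_levels <- base_levels %||% seq(40, 215, length.out = n_seg)
  if (length(base_levels) != n_seg) stop_spec("base_levels must have one level per segment")

  # per-frame mean level: start from segment levels at cuts, then apply fades
  fade_starts <- vapply(fade_spans, `[`, numeric(1), 1)
  fade_lens <- vapply(fade_spans, `[`, numeric(1), 2)
  if (length(fade_spans)) {
    spans <- rbind(
      cbind(fade_starts, fade_starts + fade_lens),
      cbind(cut_frames - 1, cut_frames)
    )
    o <- order(spans[, 1])
    spans <- spans[o, , drop = FALSE]
    if (nrow(spans) > 1 && any(spans[-1, 1] < spans[-nrow(spans), 2])) {
      stop_spec("cuts and fades overlap")
    }
    if (any(fade_starts < 1 | fade_starts + fade_lens > n_frames)) {
      stop_spec("fade span out of range")
    }
  }

  change_at <- sort(c(cut_frames, fade_starts)) # frame where each new segment begins/ramp starts
  level <- rep(base_levels[1], n_frames)
  seg <- 1L
  for (ch in change_at) {
    seg <- seg + 1L
    if (ch %in% cut_frames) {
      level[ch:n_frames] <- base_levels[seg]
    } else {
      len <- fade_lens[match(ch, fade_starts)]
      ramp <- seq(level[ch], base_levels[seg], length.out = len + 1L)
      level[(ch + 1L):(ch + len)] <- ramp[-1L]
      if (ch + len < n_frames) level[(ch + len + 1L):n_frames] <- base_levels[seg]
    }
  }
  if (length(cut_frames)) {
    jump <- abs(level[cut_frames] - level[cut_frames - 1L])
    if (any(jump < 40)) stop_spec("every abrupt cut must change mean intensity by >= 40 gray levels")
  }

  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    f <- matrix(level[i], nrow = height, ncol = width)
    if (noise_sd > 0) f <- f + matrix(rnorm(width * height, 0, noise_sd), height, width)
    pmin(pmax(floor(f + 0.5), 0), 255)
  }))

  list(
    clip = clip_frames(frames, frame_rate = frame_rate, clip_id = clip_id),
    truth = list(
      cuts = tibble(
        frame = cut_frames,
        time_ms = (cut_frames - 1L) * 1000 / frame_rate
      ),
      fades = tibble(
        start = as.integer(fade_starts),
        len = as.integer(fade_lens)
      ),
      level = level
    )
  )
}
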