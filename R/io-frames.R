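#' Construct a clip as an ordered set of grayscale frames
#'
#' @param frames list of numeric matrices with identical dimensions, values
#'   in \[0, 255\].
#' @param frame_rate frames per second.
#' @param clip_id character label.
#' @return A `clip_frames` object.
#' @export
clip_frames <- function(frames, frame_rate = 30, clip_id = "clip") {
  if (length(frames) < 2L) stop_insufficient("a clip needs at least 2 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("all frames must have identical dimensions")
  }
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 255) stop_format("frame intensities must lie in [0, 255]")
  structure(
    list(frames = frames, frame_rate = frame_rate, clip_id = clip_id),
    class = "clip_frames"
  )
}

#' @export
print.clip_frames <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "# clip '%s': %d frames of %dx%d @ %g fps\n",
    x$clip_id, length(x$frames), d[1], d[2], x$frame_rate
  ))
  invisible(x)
}

#' @export
length.clip_frames <- function(x) length(x$frames)

# BT.601 luma weights; input channels on the 0-255 scale, rounded half-up
luma_gray <- function(r, g, b) floor(0.299 * r + 0.587 * g + 0.114 * b + 0.5)

read_one_frame <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) {
      return(floor(img * 255 + 0.5))
    }
    # drop alpha if present, weight colour channels
    return(luma_gray(img[, , 1] * 255, img[, , 2] * 255, img[, , 3] * 255))
  }
  if (ext == "pgm") {
    return(read_pgm(path))
  }
  stop_format(paste0("unsupported frame format: ", path))
}

# plain (P2) portable graymap reader; P5 not supported (text fixtures only)
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  toks <- unlist(strsplit(paste(txt, collapse = " "), "[ \t]+"))
  toks <- toks[nzchar(toks)]
  if (toks[1] != "P2") stop_format(paste0("not a plain PGM (P2) file: ", path))
  vals <- as.double(toks[-1])
  w <- vals[1]; h <- vals[2]; maxv <- vals[3]
  px <- vals[-(1:3)]
  if (length(px) != w * h) stop_format(paste0("truncated PGM: ", path))
  matrix(px * (255 / maxv), nrow = h, ncol = w, byrow = TRUE)
}

#' Read a directory of image frames as a grayscale clip
#'
#' Frames are read in lexicographic filename order. Colour PNG input is
#' converted to grayscale with BT.601 luma weights (0.299, 0.587, 0.114),
#' rounded half-up; plain-text PGM (P2) is also accepted.
#'
#' @param dir directory containing `.png` and/or `.pgm` frames.
#' @param frame_rate frames per second of the source clip.
#' @param clip_id label; defaults to the directory name.
#' @return A [clip_frames()] object with intensities in \[0, 255\].
#' @export
read_frames <- function(dir, frame_rate = 30, clip_id = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(png|pgm)$", full.names = TRUE, ignore.case = TRUE))
  if (length(files) < 2L) stop_insufficient("need at least 2 frame files")
  frames <- lapply(files, read_one_frame)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("frames have mixed dimensions")
  }
  clip_frames(frames, frame_rate = frame_rate, clip_id = clip_id %||% basename(dir))
}

#' Write a clip's frames as PNG files
#'
#' Frames are written as 8-bit grayscale PNGs named `frame_0001.png`, ...,
#' so [read_frames()] recovers the clip exactly (intensities are rounded
#' to integers on write).
#'
#' @param clip a [clip_frames()] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(clip, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(clip$frames)) {
    f <- pmin(pmax(floor(clip$frames[[i]] + 0.5), 0), 255)
    png::writePNG(f / 255, file.path(dir, sprintf("frame_%04d.png", i)))
  }
  invisible(dir)
}

clip_genres <- c("drama", "comedy", "action", "documentary", "animation")

#' Read or write per-clip content-rating covariates
#'
#' Expected columns: `clip_id`; importance ratings `faces`,
#' `human_figures`, `man_made`, `nature`, `auditory` on a 0-5 scale;
#' `lighting` (ordinal); `environment` (`"indoor"`/`"outdoor"`); `genre`
#' (one of drama, comedy, action, documentary, animation).
#'
#' @param path CSV file.
#' @return A tibble of validated covariates.
#' @export
read_clip_covariates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_clip_covariates(df)
}

#' @rdname read_clip_covariates
#' @param covariates covariates tibble to write.
#' @export
write_clip_covariates <- function(covariates, path) {
  validate_clip_covariates(covariates)
  readr::write_csv(covariates, path, progress = FALSE)
  invisible(path)
}

validate_clip_covariates <- function(df) {
  rating_cols <- c("faces", "human_figures", "man_made", "nature", "auditory")
  miss <- setdiff(c("clip_id", rating_cols, "lighting", "environment", "genre"), names(df))
  if (length(miss)) stop_format(paste0("covariates missing columns: ", paste(miss, collapse = ", ")))
  for (rc in rating_cols) {
    v <- df[[rc]]
    if (any(v < 0 | v > 5, na.rm = TRUE)) stop_format(paste0("rating out of [0,5]: ", rc))
  }
  if (!all(df$genre %in% clip_genres)) {
    stop_format(paste0("unknown genre: ", paste(setdiff(df$genre, clip_genres), collapse = ", ")))
  }
  if (!all(df$environment %in% c("indoor", "outdoor"))) {
    stop_format("environment must be 'indoor' or 'outdoor'")
  }
  as_tibble(df)
}
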