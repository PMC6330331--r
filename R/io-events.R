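# canonical saccade-event table columns, in file order
saccade_table_cols <- c(
  "trace_id", "onset_ms", "offset_ms", "duration_ms",
  "magnitude", "path_length", "peak_velocity", "direction",
  "orientation", "leftward", "downward",
  "accepted", "rejection_reason",
  "curvature", "p1", "p2", "p3", "deviation", "converged",
  "inflight_cut", "session_offset_ms"
)

saccade_col_types <- readr::cols(
  trace_id = readr::col_character(),
  onset_ms = readr::col_double(), offset_ms = readr::col_double(),
  duration_ms = readr::col_double(), magnitude = readr::col_double(),
  path_length = readr::col_double(), peak_velocity = readr::col_double(),
  direction = readr::col_double(), orientation = readr::col_character(),
  leftward = readr::col_logical(), downward = readr::col_logical(),
  accepted = readr::col_logical(), rejection_reason = readr::col_character(),
  curvature = readr::col_double(), p1 = readr::col_double(),
  p2 = readr::col_double(), p3 = readr::col_double(),
  deviation = readr::col_double(), converged = readr::col_logical(),
  inflight_cut = readr::col_logical(), session_offset_ms = readr::col_double()
)

# fill any missing canonical columns with NA of the right type
complete_saccade_cols <- function(events) {
  proto <- list(
    trace_id = NA_character_, onset_ms = NA_real_, offset_ms = NA_real_,
    duration_ms = NA_real_, magnitude = NA_real_, path_length = NA_real_,
    peak_velocity = NA_real_, direction = NA_real_,
    orientation = NA_character_, leftward = NA, downward = NA,
    accepted = NA, rejection_reason = NA_character_,
    curvature = NA_real_, p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
    deviation = NA_real_, converged = NA, inflight_cut = NA,
    session_offset_ms = NA_real_
  )
  for (nm in saccade_table_cols) {
    if (!nm %in% names(events)) events[[nm]] <- rep(proto[[nm]], nrow(events))
  }
  events[saccade_table_cols]
}

#' Write and read saccade event tables
#'
#' One row per saccade, fixed column order, full float precision; a
#' write/read round trip is lossless.
#'
#' @param events tibble of saccade events (see [detect_saccades()]).
#' @param path CSV file.
#' @return `write_saccade_table()` returns `path` invisibly;
#'   `read_saccade_table()` returns the events tibble.
#' @export
write_saccade_table <- function(events, path) {
  events <- complete_saccade_cols(as_tibble(events))
  readr::write_csv(events, path, progress = FALSE, na = "")
  invisible(path)
}

#' @rdname write_saccade_table
#' @export
read_saccade_table <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  df <- suppressWarnings(readr::read_csv(path,
    col_types = saccade_col_types, na = "", progress = FALSE
  ))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop_format(sprintf("malformed saccade table at line %d", probs$row[1]))
  }
  df
}
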