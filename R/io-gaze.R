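#' Read a gaze trace from disk
#'
#' Two dialects are supported. `"csv"` expects a header
#' `t_ms,x_deg,y_deg,valid` (comma separator, `.` decimal, UTF-8); `valid`
#' is 0/1. `"eyelink_asc_subset"` reads the whitespace-separated sample
#' lines `<t> <x> <y> <pupil>` of an EyeLink ASC export, with `.` marking
#' missing values; no event or message lines are parsed.
#'
#' Internally y is positive upward. Screen-style inputs with y growing
#' downward are flipped at read time via `y_down`; the package's own CSV
#' dialect stores y upward (`y_down = FALSE`), while EyeLink screen
#' coordinates default to `y_down = TRUE`.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"eyelink_asc_subset"`.
#' @param y_down logical; flip the sign of y on input. Defaults to `FALSE`
#'   for `"csv"` and `TRUE` for `"eyelink_asc_subset"`.
#' @param trace_id,session_offset_ms metadata attached to the trace.
#' @return A [gaze_trace()].
#' @export
read_gaze <- function(path, dialect = c("csv", "eyelink_asc_subset"),
                      y_down = NULL, trace_id = NULL, session_offset_ms = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  trace_id <- trace_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "csv") {
    y_down <- y_down %||% FALSE
    df <- suppressWarnings(readr::read_csv(path,
      col_types = readr::cols(
        t_ms = readr::col_double(), x_deg = readr::col_double(),
        y_deg = readr::col_double(), valid = readr::col_double()
      ),
      progress = FALSE
    ))
    probs <- readr::problems(df)
    if (nrow(probs)) {
      stop_format(sprintf(
        "malformed gaze CSV at line %d: expected %s", probs$row[1], probs$expected[1]
      ))
    }
    miss <- setdiff(c("t_ms", "x_deg", "y_deg", "valid"), names(df))
    if (length(miss)) stop_format(paste0("gaze CSV missing columns: ", paste(miss, collapse = ", ")))
    valid <- df$valid != 0 & !is.na(df$x_deg) & !is.na(df$y_deg)
    x <- ifelse(is.na(df$x_deg), 0, df$x_deg)
    y <- ifelse(is.na(df$y_deg), 0, df$y_deg)
    tm <- df$t_ms
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(toks) != 4L)
    if (length(bad)) stop_format(sprintf("malformed ASC sample at line %d", bad[1]))
    fields <- function(i) vapply(toks, `[[`, "", i)
    num_or_na <- function(v) suppressWarnings(as.double(ifelse(v == ".", NA, v)))
    tm <- num_or_na(fields(1L))
    if (anyNA(tm)) stop_format(sprintf("missing timestamp at line %d", which(is.na(tm))[1]))
    xr <- num_or_na(fields(2L))
    yr <- num_or_na(fields(3L))
    valid <- !(is.na(xr) | is.na(yr))
    x <- ifelse(valid, xr, 0)
    y <- ifelse(valid, yr, 0)
    y_down <- y_down %||% TRUE
  }
  if (y_down) y <- -y
  gaze_trace(tm, x, y, valid,
    trace_id = trace_id, session_offset_ms = session_offset_ms
  )
}

#' Write a gaze trace to the package CSV dialect
#'
#' Columns `t_ms,x_deg,y_deg,valid` with y positive upward and full float
#' precision, so a write/read round trip reproduces the trace exactly.
#'
#' @param trace a [gaze_trace()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(trace, path) {
  df <- tibble(
    t_ms = trace$time_ms, x_deg = trace$x, y_deg = trace$y,
    valid = as.integer(trace$valid)
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
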