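#' Recode a 0-5 content-importance rating into low / medium / high
#'
#' A clip has high content when the average rating is 4 or greater, low
#' when it is 1 or less, and medium otherwise (ratings of 2-3).
#'
#' @param rating numeric rating(s) in \[0, 5\].
#' @return A factor with levels low, medium, high.
#' @export
#' @examples
#' content_level(c(0.5, 1, 1.5, 3, 4, 4.5))
content_level <- function(rating) {
  if (any(rating < 0 | rating > 5, na.rm = TRUE)) stop_format("ratings must lie in [0, 5]")
  factor(
    ifelse(rating <= 1, "low", ifelse(rating >= 4, "high", "medium")),
    levels = c("low", "medium", "high")
  )
}

#' Build the saccade-level analysis table
#'
#' One row per accepted saccade, ready for regression modelling: base-10
#' logs of curvature, velocity-profile deviation and duration with their
#' exact squares and cubes; one-hot orientation dummies (horizontal is
#' the reference category); leftward/downward direction indicators
#' (rightward/upward reference); the in-flight-cut flag; and the
#' time-on-task bin, the ordinal 30-second interval of the session the
#' saccade occurred in (`1 + floor(session_offset_ms / 30000)`). Clip and
#' subject covariates are joined on `clip_id` / `subject_id` when given;
#' content ratings are recoded with [content_level()]. Rows with
#' nonpositive curvature or deviation cannot be log-transformed and are
#' dropped with a message reporting the count.
#'
#' @param events saccade-event tibble with metrics filled
#'   (see [add_saccade_metrics()]).
#' @param clip_covariates optional tibble from [read_clip_covariates()];
#'   requires a `clip_id` column on `events`.
#' @param subject_covariates optional tibble with columns `subject_id`,
#'   `age` (years), `gender`, `education` (ISCED level 1-7); requires a
#'   `subject_id` column on `events`.
#' @return The analysis tibble.
#' @export
build_analysis_table <- function(events, clip_covariates = NULL,
                                 subject_covariates = NULL) {
  ev <- events[!is.na(events$accepted) & events$accepted, , drop = FALSE]
  need <- c("curvature", "deviation", "duration_ms")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop_format(paste0("events lack metric columns: ", paste(miss, collapse = ", ")))
  usable <- !is.na(ev$curvature) & !is.na(ev$deviation) &
    ev$curvature > 0 & ev$deviation > 0 & ev$duration_ms > 0
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message(sprintf("dropping %d saccade(s) with nonpositive or missing curvature/deviation", n_dropped))
  }
  ev <- ev[usable, , drop = FALSE]
  if (!"inflight_cut" %in% names(ev)) ev$inflight_cut <- NA
  out <- mutate(ev,
    log_k = log10(.data$curvature),
    log_k2 = .data$log_k^2, log_k3 = .data$log_k^3,
    log_dev = log10(.data$deviation),
    log_dev2 = .data$log_dev^2, log_dev3 = .data$log_dev^3,
    log_dur = log10(.data$duration_ms),
    log_dur2 = .data$log_dur^2, log_dur3 = .data$log_dur^3,
    orient_horizontal = as.integer(.data$orientation == "horizontal"),
    orient_vertical = as.integer(.data$orientation == "vertical"),
    orient_oblique = as.integer(.data$orientation == "oblique"),
    leftward = as.integer(.data$leftward),
    downward = as.integer(.data$downward),
    inflight_cut = as.integer(.data$inflight_cut),
    time_on_task_bin = 1L + as.integer(floor(.data$session_offset_ms / 30000))
  )
  if (!is.null(clip_covariates)) {
    if (!"clip_id" %in% names(out)) stop_format("events need a clip_id column to join clip covariates")
    missing_ids <- setdiff(unique(out$clip_id), clip_covariates$clip_id)
    if (length(missing_ids)) {
      abort(paste0(
        "clip covariates missing for: ", paste(missing_ids, collapse = ", ")
      ), class = "saccurv_error_join")
    }
    cc <- mutate(as_tibble(clip_covariates),
      faces_level = content_level(.data$faces),
      human_figures_level = content_level(.data$human_figures),
      man_made_level = content_level(.data$man_made),
      nature_level = content_level(.data$nature),
      auditory_level = content_level(.data$auditory),
      genre = factor(.data$genre, levels = c("comedy", setdiff(clip_genres, "comedy")))
    )
    out <- left_join(out, cc, by = "clip_id")
  }
  if (!is.null(subject_covariates)) {
    if (!"subject_id" %in% names(out)) stop_format("events need a subject_id column to join subject covariates")
    missing_ids <- setdiff(unique(out$subject_id), subject_covariates$subject_id)
    if (length(missing_ids)) {
      abort(paste0(
        "subject covariates missing for: ", paste(missing_ids, collapse = ", ")
      ), class = "saccurv_error_join")
    }
    out <- left_join(out, as_tibble(subject_covariates), by = "subject_id")
  }
  as_tibble(out)
}

#' Univariable cubic polynomial fit on log-log scales
#'
#' Ordinary least squares of a (log-transformed) outcome on a
#' (log-transformed) predictor with its square and cube — the standard
#' summary of the nonlinear curvature-deviation-duration relationships.
#'
#' @param data a data frame (e.g. from [build_analysis_table()]).
#' @param response,predictor column names (tidy-eval, unquoted or strings).
#' @return A `log_cubic_fit` (wraps `lm`); supports `tidy()`, `glance()`
#'   and `autoplot()`.
#' @export
#' @examples
#' df <- data.frame(x = seq(-1, 1, length.out = 50))
#' df$y <- 2 + 3 * df$x - df$x^2 + 0.5 * df$x^3
#' coef(fit_log_cubic(df, y, x)$fit)
fit_log_cubic <- function(data, response, predictor) {
  y_col <- as_name(enquo(response))
  x_col <- as_name(enquo(predictor))
  df <- tibble(y = data[[y_col]], x = data[[x_col]])
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 5L) stop_insufficient("cubic fit needs at least 5 complete observations")
  if (sd(df$x) == 0) {
    abort("degenerate predictor: no variation", class = "saccurv_error_degenerate")
  }
  fit <- lm(y ~ x + I(x^2) + I(x^3), data = df)
  structure(list(
    fit = fit, data = df, response = y_col, predictor = x_col
  ), class = "log_cubic_fit")
}

#' @export
print.log_cubic_fit <- function(x, ...) {
  cf <- coef(x$fit)
  cat(sprintf(
    "# cubic fit: %s = %.4g %+.4g %s %+.4g %s^2 %+.4g %s^3  (n = %d, R^2 = %.3f)\n",
    x$response, cf[1], cf[2], x$predictor, cf[3], x$predictor, cf[4], x$predictor,
    nrow(x$data), summary(x$fit)$r.squared
  ))
  invisible(x)
}

#' @method tidy log_cubic_fit
#' @export
tidy.log_cubic_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", x$predictor, paste0(x$predictor, "^2"), paste0(x$predictor, "^3")),
    estimate = unname(s[, 1]), std_error = unname(s[, 2]),
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' @method glance log_cubic_fit
#' @export
glance.log_cubic_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = nrow(x$data), r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared, sigma = s$sigma
  )
}

#' @method autoplot log_cubic_fit
#' @export
autoplot.log_cubic_fit <- function(object, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x), length.out = 200))
  grid$y <- predict(object$fit, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.7) +
    ggplot2::labs(x = object$predictor, y = object$response,
                  title = "univariable cubic fit") +
    ggplot2::theme_minimal()
}

#' Export the model-ready analysis table
#'
#' Writes the analysis table as CSV with documented column coding so any
#' linear-mixed-model tool can fit crossed random effects for subject and
#' clip. Before writing, the polynomial columns are asserted to equal the
#' exact powers of their base terms.
#'
#' @param rows tibble from [build_analysis_table()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
export_model_table <- function(rows, path) {
  for (base in c("log_k", "log_dev", "log_dur")) {
    if (!base %in% names(rows)) next
    if (!isTRUE(all.equal(rows[[paste0(base, "2")]], rows[[base]]^2, tolerance = 1e-12)) ||
        !isTRUE(all.equal(rows[[paste0(base, "3")]], rows[[base]]^3, tolerance = 1e-12))) {
      stop_format(paste0("polynomial columns of ", base, " are not exact powers"))
    }
  }
  readr::write_csv(rows, path, progress = FALSE, na = "")
  invisible(path)
}
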