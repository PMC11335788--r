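# Input/output conventions: the per-movie event cache, gaze CSV ingestion,
# and the parameter / prediction result CSVs.

cache_name <- function(movie, subject, grid)
  sprintf("%s_%s_VF_LAB_%dX%d.json", movie, subject, grid$rows, grid$cols)

#' Write an event-trace cache
#'
#' Serializes extracted event traces (metadata, timestamps, and the
#' per-region luminance and contrast matrices) as JSON to
#' `"<dir>/<movie>_<subject>_VF_LAB_<rows>X<cols>.json"`.
#'
#' @param traces An [event_traces()] object.
#' @param movie,subject Names used in the file name.
#' @param dir Output directory (default `"Visual events"`, created if
#'   missing).
#' @return The path written, invisibly.
#' @export
write_event_cache <- function(traces, movie, subject, dir = "Visual events") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, cache_name(movie, subject, traces$grid))
  payload <- list(movie = movie, subject = subject,
                  width = traces$width, height = traces$height,
                  fps = traces$fps, mode = traces$mode,
                  grid = list(rows = traces$grid$rows, cols = traces$grid$cols),
                  timestamps = traces$timestamps,
                  luminance_change = traces$luminance_change)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an event-trace cache written by [write_event_cache()]
#'
#' @param path Path to the JSON cache.
#' @return An [event_traces()] object.
#' @export
read_event_cache <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  event_traces(x$timestamps, x$luminance_change, mode = x$mode,
               grid = region_grid(x$grid$rows, x$grid$cols), fps = x$fps,
               width = x$width, height = x$height)
}

#' Export event traces as plain CSV
#'
#' One row per frame: `timestamp`, signed luminance change per region
#' (`lum_1` ... `lum_R`) and contrast change per region (`con_1` ...).
#'
#' @param traces An [event_traces()] object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_event_csv <- function(traces, path) {
  R <- ncol(traces$luminance_change)
  df <- data.frame(timestamp = traces$timestamps,
                   traces$luminance_change, traces$contrast_change)
  names(df) <- c("timestamp", paste0("lum_", seq_len(R)),
                 paste0("con_", seq_len(R)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an eye-tracking CSV
#'
#' Expects a header row with timestamp, gaze-x, gaze-y and pupil columns
#' (pixel coordinates, origin top-left). Samples with non-finite coordinates
#' are flagged invalid in the gaze trace; samples with non-finite or
#' non-positive pupil size are flagged invalid in the recording.
#'
#' @param path CSV path.
#' @param time_unit `"s"` or `"ms"` for the timestamp column.
#' @param timestamp_col,x_col,y_col,pupil_col Column names.
#' @return List with elements `gaze` (a [gaze_trace()]) and `recording`
#'   (a [recording()]).
#' @export
read_gaze_csv <- function(path, time_unit = c("s", "ms"),
                          timestamp_col = "timestamp", x_col = "gaze_x",
                          y_col = "gaze_y", pupil_col = "pupil") {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path)
  need <- c(timestamp_col, x_col, y_col, pupil_col)
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  ts <- df[[timestamp_col]] / if (time_unit == "ms") 1000 else 1
  ts <- ts - ts[1L]
  x <- df[[x_col]]; y <- df[[y_col]]; p <- df[[pupil_col]]
  list(gaze = gaze_trace(ts, x, y, valid = is.finite(x) & is.finite(y)),
       recording = recording(ts, p, valid = is.finite(p) & p > 0))
}

#' Write the fitted-parameter CSV
#'
#' Two columns (`parameter`, `value`): the across-fold mean of every free
#' parameter followed by performance rows (correlation, RMSE, R-squared,
#' BIC), written to `"<dir>/<movie>_<subject>_parameters.csv"`.
#'
#' @param fit A `plr_fit` from [fit()].
#' @param movie,subject Names used in the file name.
#' @param dir Output directory (default `"csv results"`).
#' @return The path written, invisibly.
#' @export
write_parameters_csv <- function(fit, movie, subject, dir = "csv results") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_parameters.csv", movie, subject))
  p <- colMeans(fit$param_per_fold)
  df <- data.frame(parameter = c(names(p), "correlation", "RMSE", "R2", "BIC"),
                   value = c(unname(p), fit$summary$test_r_mean,
                             fit$summary$test_rmse_mean,
                             fit$summary$test_r2_mean,
                             fit$summary$test_bic_mean))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the model-prediction CSV
#'
#' Columns `actual_pupil` (z-scored observation interpolated onto the
#' prediction timestamps), `predicted_combined`, `predicted_luminance`,
#' `predicted_contrast`, written to
#' `"<dir>/<movie>_<subject>_modelPrediction.csv"`.
#'
#' @param prediction A `pupil_prediction` from [predict_pupil()].
#' @param rec The matching [recording()].
#' @param movie,subject Names used in the file name.
#' @param dir Output directory (default `"csv results"`).
#' @return The path written, invisibly.
#' @export
write_prediction_csv <- function(prediction, rec, movie, subject,
                                 dir = "csv results") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_modelPrediction.csv", movie, subject))
  obs <- interpolate_pupil(rec, prediction$timestamps)
  df <- data.frame(timestamp = prediction$timestamps,
                   actual_pupil = zscore(obs),
                   predicted_combined = prediction$combined,
                   predicted_luminance = prediction$luminance_only,
                   predicted_contrast = prediction$contrast_only)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a pupil prediction against the observed trace
#'
#' @param x A `pupil_prediction`.
#' @param rec Optional matching [recording()]; its z-scored trace is drawn
#'   behind the prediction.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.pupil_prediction <- function(x, rec = NULL, ...) {
  graphics::plot(x$timestamps, x$combined, type = "n",
                 xlab = "time (s)", ylab = "pupil size (z)", ...)
  if (!is.null(rec)) {
    obs <- zscore(interpolate_pupil(rec, x$timestamps))
    graphics::lines(x$timestamps, obs, col = "grey60")
  }
  graphics::lines(x$timestamps, x$combined, col = "brown")
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c("grey60", "brown"),
                   legend = c("observed", "predicted"))
  invisible(x)
}

#' Export a prediction plot to a PNG file
#'
#' @param prediction A `pupil_prediction`.
#' @param rec Optional matching [recording()].
#' @param file Output PNG path.
#' @param width,height,res Device settings.
#' @return The path, invisibly.
#' @export
export_prediction_plot <- function(prediction, rec = NULL, file,
                                   width = 1200, height = 400, res = 120) {
  grDevices::png(file, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  plot(prediction, rec = rec)
  invisible(file)
}
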