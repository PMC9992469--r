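#' Time-activity curves
#'
#' A time-activity curve (TAC) is a tibble with a strictly increasing `time_s`
#' column (seconds) and an `activity_Bq_ml` column (activity concentration in
#' Bq/ml). All curve-handling functions in the package accept any data frame
#' with these two columns and return a `pet_curve` tibble.
#'
#' @param time_s Sample times (s), strictly increasing.
#' @param activity_Bq_ml Activity concentrations (Bq/ml), finite.
#' @return A tibble of class `pet_curve`.
#' @examples
#' pet_curve(c(0, 1, 2), c(0, 10, 5))
#' @export
pet_curve <- function(time_s, activity_Bq_ml) {
  time_s <- as.numeric(time_s)
  activity_Bq_ml <- as.numeric(activity_Bq_ml)
  if (length(time_s) != length(activity_Bq_ml)) {
    abort("`time_s` and `activity_Bq_ml` must have the same length.",
          class = "widif_schema_error")
  }
  if (any(!is.finite(time_s)) || any(!is.finite(activity_Bq_ml))) {
    abort("Curve times and values must be finite.", class = "widif_validation_error")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    abort("Curve times must be strictly increasing (no duplicates).",
          class = "widif_validation_error")
  }
  new_tibble(list(time_s = time_s, activity_Bq_ml = activity_Bq_ml),
             nrow = length(time_s), class = "pet_curve")
}

as_pet_curve <- function(x) {
  if (!is.data.frame(x) || !all(c("time_s", "activity_Bq_ml") %in% names(x))) {
    abort("Expected a curve (columns time_s, activity_Bq_ml).",
          class = "widif_schema_error")
  }
  ord <- order(x$time_s)
  pet_curve(x$time_s[ord], x$activity_Bq_ml[ord])
}

#' Read or write a time-activity curve as TSV
#'
#' Tab-separated with header columns `time_s` and `activity_Bq_ml`. Rows are
#' sorted by time on read; duplicated times are rejected.
#'
#' @param path File path.
#' @return `read_curve()` returns a [pet_curve()]; `write_curve()` returns
#'   `path` invisibly.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path), class = "widif_io_error")
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  if (!all(c("time_s", "activity_Bq_ml") %in% names(df))) {
    abort("Curve TSV must have columns time_s and activity_Bq_ml.",
          class = "widif_schema_error")
  }
  as_pet_curve(df)
}

#' @rdname read_curve
#' @param curve A curve (data frame with `time_s`, `activity_Bq_ml`).
#' @export
write_curve <- function(curve, path) {
  curve <- as_pet_curve(curve)
  write.table(as.data.frame(curve), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

# Linear interpolation of a curve at times tt; error outside support unless
# rule permits extension.
curve_interp <- function(curve, tt, rule = 1) {
  curve <- as_pet_curve(curve)
  if (nrow(curve) < 2) abort("Need at least two samples to interpolate.",
                             class = "widif_validation_error")
  approx(curve$time_s, curve$activity_Bq_ml, xout = tt, rule = rule)$y
}

#' Area under a curve between two times
#'
#' Trapezoidal integral of the linear interpolant of the curve over
#' `[t0, t1]`, with interpolated endpoint values at exactly `t0` and `t1`.
#'
#' @param curve A curve (data frame with `time_s`, `activity_Bq_ml`).
#' @param t0,t1 Integration window (s); must satisfy `t0 < t1` and lie within
#'   the curve's support.
#' @return Scalar AUC in Bq s/ml.
#' @examples
#' auc(pet_curve(c(0, 10), c(0, 10)), 0, 10) # 50
#' @export
auc <- function(curve, t0, t1) {
  curve <- as_pet_curve(curve)
  if (t1 <= t0) abort("`t1` must exceed `t0`.", class = "widif_validation_error")
  tmin <- curve$time_s[1]; tmax <- curve$time_s[nrow(curve)]
  if (t0 < tmin - 1e-9 || t1 > tmax + 1e-9) {
    abort("Integration window lies outside the curve's support.",
          class = "widif_validation_error")
  }
  inner <- curve$time_s[curve$time_s > t0 & curve$time_s < t1]
  tt <- c(t0, inner, t1)
  vv <- curve_interp(curve, tt)
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
}

#' Resample a curve onto a frame schedule
#'
#' For each frame the linear interpolant of the curve is averaged over
#' `[start, start + duration]`; the resampled value is stamped at the frame
#' mid-time. This is how a densely sampled blood curve is brought onto the
#' PET frame grid.
#'
#' @param curve A curve whose support covers the whole schedule span.
#' @param schedule A [frame_schedule()].
#' @return A [pet_curve()] with one sample per frame.
#' @export
resample_to_frames <- function(curve, schedule) {
  curve <- as_pet_curve(curve)
  schedule <- as_frame_schedule(schedule)
  if (!nrow(schedule)) return(pet_curve(numeric(0), numeric(0)))
  tmin <- curve$time_s[1]; tmax <- curve$time_s[nrow(curve)]
  ends <- schedule$start_s + schedule$duration_s
  if (min(schedule$start_s) < tmin - 1e-9 || max(ends) > tmax + 1e-9) {
    abort("Schedule extends beyond the curve's support.",
          class = "widif_validation_error")
  }
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    auc(curve, schedule$start_s[i], ends[i]) / schedule$duration_s[i]
  }, numeric(1))
  pet_curve(frame_mid_times(schedule), vals)
}

#' @method autoplot pet_curve
#' @export
autoplot.pet_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$activity_Bq_ml)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (s)", y = "Activity (Bq/ml)")
}
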