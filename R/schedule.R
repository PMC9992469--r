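#' Frame schedules
#'
#' A frame schedule records, for every reconstructed frame of a dynamic PET
#' scan, its start time and duration in seconds. Frames must not overlap and
#' durations must be positive; starts are non-decreasing.
#'
#' @param start_s Numeric vector of frame start times (s).
#' @param duration_s Numeric vector of frame durations (s), same length.
#'
#' @return A tibble of class `frame_schedule` with columns `start_s` and
#'   `duration_s`.
#' @examples
#' frame_schedule(c(0, 5, 10), c(5, 5, 10))
#' @export
frame_schedule <- function(start_s, duration_s) {
  start_s <- as.numeric(start_s)
  duration_s <- as.numeric(duration_s)
  if (length(start_s) != length(duration_s)) {
    abort("`start_s` and `duration_s` must have the same length.", class = "widif_schema_error")
  }
  if (length(start_s)) {
    if (any(!is.finite(start_s)) || any(!is.finite(duration_s))) {
      abort("Frame times must be finite.", class = "widif_validation_error")
    }
    if (any(duration_s <= 0)) {
      abort("Frame durations must be positive.", class = "widif_validation_error")
    }
    if (any(diff(start_s) < 0)) {
      abort("Frame starts must be non-decreasing.", class = "widif_validation_error")
    }
    ends <- start_s + duration_s
    if (length(start_s) > 1 && any(start_s[-1] < ends[-length(ends)] - 1e-6)) {
      abort("Frames overlap.", class = "widif_validation_error")
    }
  }
  new_tibble(list(start_s = start_s, duration_s = duration_s),
             nrow = length(start_s),
             class = "frame_schedule")
}

#' Standard 26-frame schedule for a bolus water scan
#'
#' The variable-duration framing commonly used for a 10-min dynamic
#' \eqn{^{15}}O-water acquisition: 8 x 5 s, 4 x 10 s, 1 x 15 s, 4 x 20 s,
#' 2 x 30 s, 7 x 60 s (26 frames, 655 s total).
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  durations <- c(rep(5, 8), rep(10, 4), 15, rep(20, 4), rep(30, 2), rep(60, 7))
  frame_schedule(cumsum(c(0, durations[-length(durations)])), durations)
}

#' Frame mid-point times
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector `start_s + duration_s / 2`, one value per frame.
#' @examples
#' frame_mid_times(frame_schedule(0, 5)) # 2.5
#' @export
frame_mid_times <- function(schedule) {
  schedule <- as_frame_schedule(schedule)
  schedule$start_s + schedule$duration_s / 2
}

as_frame_schedule <- function(x) {
  if (inherits(x, "frame_schedule")) return(x)
  if (is.data.frame(x) && all(c("start_s", "duration_s") %in% names(x))) {
    return(frame_schedule(x$start_s, x$duration_s))
  }
  abort("Expected a frame schedule (columns start_s, duration_s).",
        class = "widif_schema_error")
}

#' Read or write a frame-schedule sidecar
#'
#' NIfTI-1 carries no per-frame timing, so the schedule lives in a JSON
#' sidecar with fields `frame_start_s` and `frame_duration_s`.
#'
#' @param path Path of the JSON sidecar.
#' @return `read_frame_schedule()` returns a [frame_schedule()];
#'   `write_frame_schedule()` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path), class = "widif_io_error")
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$frame_start_s) || is.null(js$frame_duration_s)) {
    abort("Schedule sidecar must contain frame_start_s and frame_duration_s.",
          class = "widif_schema_error")
  }
  frame_schedule(js$frame_start_s, js$frame_duration_s)
}

#' @rdname read_frame_schedule
#' @param schedule A [frame_schedule()].
#' @export
write_frame_schedule <- function(schedule, path) {
  schedule <- as_frame_schedule(schedule)
  jsonlite::write_json(list(frame_start_s = schedule$start_s,
                            frame_duration_s = schedule$duration_s),
                       path, digits = NA)
  invisible(path)
}
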