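#' Calibrate an online blood curve to discrete samples
#'
#' The continuously sampled curve is scaled by a single multiplicative
#' factor: the mean over the discrete well-counter samples of
#' (sample value / curve value at the sample time), with the curve value
#' taken from linear interpolation. Two late samples (e.g. at 5 and 10 min)
#' are typical.
#'
#' @param curve Online sampler curve (data frame with `time_s`,
#'   `activity_Bq_ml`).
#' @param samples Data frame with columns `time_s` and `activity_Bq_ml`
#'   (the well-counter measurements), at least one row; times must lie
#'   within the curve support.
#' @return A list with `curve` (the scaled [pet_curve()]) and `factor`.
#' @export
calibrate_curve <- function(curve, samples) {
  curve <- as_pet_curve(curve)
  if (!is.data.frame(samples) ||
      !all(c("time_s", "activity_Bq_ml") %in% names(samples)) ||
      !nrow(samples)) {
    abort("`samples` must be a non-empty data frame with time_s, activity_Bq_ml.",
          class = "widif_schema_error")
  }
  if (min(samples$time_s) < min(curve$time_s) - 1e-9 ||
      max(samples$time_s) > max(curve$time_s) + 1e-9) {
    abort("Sample times lie outside the curve support.",
          class = "widif_validation_error")
  }
  at <- curve_interp(curve, samples$time_s)
  if (any(at <= 0)) {
    abort("Curve value is zero at a calibration sample time.",
          class = "widif_validation_error")
  }
  factor <- mean(samples$activity_Bq_ml / at)
  list(curve = pet_curve(curve$time_s, curve$activity_Bq_ml * factor),
       factor = factor)
}

#' Dispersion-correct a sampled blood curve
#'
#' Inverts the monoexponential dispersion of the sampling line and
#' vasculature: if the measured curve is the true curve convolved with
#' `(1/tau) exp(-t/tau)`, then `c_true(t) = c_meas(t) + tau * dc_meas/dt`.
#' The derivative term amplifies noise, so the curve is pre-smoothed with a
#' 3-sample moving average before a 3-point central difference (one-sided at
#' the ends). `tau_s = 0` is the identity. The default time constant of 13 s
#' combines typical line (8 s) and body (5 s) dispersion.
#'
#' @param curve Densely (about 1 s) and uniformly sampled curve.
#' @param tau_s Dispersion time constant (s, >= 0), default 13.
#' @return A [pet_curve()].
#' @export
dispersion_correct <- function(curve, tau_s = 13) {
  curve <- as_pet_curve(curve)
  if (tau_s < 0) abort("`tau_s` must be >= 0.", class = "widif_validation_error")
  if (tau_s == 0) return(curve)
  n <- nrow(curve)
  if (n < 3) abort("Need at least 3 samples for the derivative.",
                   class = "widif_validation_error")
  v <- curve$activity_Bq_ml
  sm <- v
  sm[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  t <- curve$time_s
  dv <- numeric(n)
  dv[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  dv[1] <- (sm[2] - sm[1]) / (t[2] - t[1])
  dv[n] <- (sm[n] - sm[n - 1]) / (t[n] - t[n - 1])
  pet_curve(t, v + tau_s * dv)
}

#' Apply monoexponential dispersion to a curve
#'
#' Forward model used in round-trip validation of [dispersion_correct()]:
#' convolves the curve with the kernel `(1/tau) exp(-t/tau)` (exactly, for
#' the piecewise-linear interpolant).
#'
#' @inheritParams dispersion_correct
#' @return A [pet_curve()].
#' @export
apply_dispersion <- function(curve, tau_s = 13) {
  curve <- as_pet_curve(curve)
  if (tau_s < 0) abort("`tau_s` must be >= 0.", class = "widif_validation_error")
  if (tau_s == 0) return(curve)
  disp <- exp_convolve(curve$time_s, curve$activity_Bq_ml, 1 / tau_s) / tau_s
  pet_curve(curve$time_s, disp)
}

#' Estimate the blood-sampling delay against a reference TAC
#'
#' Grid search for the transit delay between the sampling site and the
#' brain: the candidate delay (from `delays`) that minimises the sum of
#' squared differences between the time-shifted, peak-normalised curve and
#' the peak-normalised reference over the first `window_s` seconds. Positive
#' delay means the blood curve lags the reference.
#'
#' @param curve Sampled blood curve.
#' @param reference_tac Reference tissue or head curve.
#' @param delays Candidate delays (s), default `seq(-5, 15, by = 0.5)`.
#' @param window_s Comparison window from time zero (default 60 s).
#' @return The best delay (s), always an element of `delays`.
#' @export
estimate_delay <- function(curve, reference_tac, delays = seq(-5, 15, by = 0.5),
                           window_s = 60) {
  curve <- as_pet_curve(curve)
  reference_tac <- as_pet_curve(reference_tac)
  lo <- max(min(curve$time_s), min(reference_tac$time_s))
  hi <- min(max(curve$time_s), max(reference_tac$time_s))
  if (hi <= lo) abort("Curve and reference supports do not overlap.",
                      class = "widif_validation_error")
  tt <- seq(max(0, lo), min(window_s, hi), by = 0.5)
  ref <- curve_interp(reference_tac, tt, rule = 2)
  ref <- ref / max(abs(ref), 1e-12)
  sse <- vapply(delays, function(d) {
    shifted <- curve_interp(curve, tt + d, rule = 2)
    shifted <- shifted / max(abs(shifted), 1e-12)
    sum((shifted - ref)^2)
  }, numeric(1))
  delays[which.min(sse)]
}

#' Shift a curve earlier by a measured delay
#'
#' For a positive measured delay the curve is moved earlier in time:
#' values are re-interpolated onto the original time stamps from
#' `time + delay`, zero-filled before tracer appearance. Support shifted
#' before time zero is truncated with a warning.
#'
#' @param curve A curve.
#' @param delay_s Measured delay (s); positive shifts the curve earlier.
#' @return A [pet_curve()] on the original time grid.
#' @export
shift_curve <- function(curve, delay_s) {
  curve <- as_pet_curve(curve)
  if (delay_s == 0) return(curve)
  vals <- approx(curve$time_s, curve$activity_Bq_ml,
                 xout = curve$time_s + delay_s, rule = 1)$y
  vals[is.na(vals)] <- 0
  if (delay_s > 0 && curve$activity_Bq_ml[1] != 0 && curve$time_s[1] <= 0) {
    warn("Curve support shifted before t = 0 was truncated.")
  }
  pet_curve(curve$time_s, vals)
}

#' Prepare a blood-sampled input function
#'
#' Conditions a raw online sampler curve for kinetic modelling: scale to the
#' discrete calibration samples, correct dispersion (tau default 13 s),
#' estimate and remove the delay against a reference TAC, and resample onto
#' the PET frame schedule.
#'
#' @param curve Raw sampler curve (about 1-s sampling).
#' @param samples Calibration samples (see [calibrate_curve()]), or `NULL`
#'   to skip.
#' @param schedule Target [frame_schedule()].
#' @param reference_tac Reference TAC for delay estimation, or `NULL` to
#'   skip delay correction.
#' @param tau_s Dispersion constant (s), default 13.
#' @param delays Candidate delay grid (s).
#' @return A list with `bsif` (frame-resampled [pet_curve()]), `curve`
#'   (conditioned dense curve), `calibration_factor` and `delay_s`.
#' @export
prepare_bsif <- function(curve, samples = NULL, schedule,
                         reference_tac = NULL, tau_s = 13,
                         delays = seq(-5, 15, by = 0.5)) {
  curve <- as_pet_curve(curve)
  factor <- NA_real_
  if (!is.null(samples)) {
    cal <- calibrate_curve(curve, samples)
    curve <- cal$curve
    factor <- cal$factor
  }
  curve <- dispersion_correct(curve, tau_s)
  delay <- 0
  if (!is.null(reference_tac)) {
    delay <- estimate_delay(curve, reference_tac, delays)
    curve <- shift_curve(curve, delay)
  }
  list(bsif = resample_to_frames(curve, schedule), curve = curve,
       calibration_factor = factor, delay_s = delay)
}
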