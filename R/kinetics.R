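#' Default clearance-rate grid
#'
#' 100 logarithmically spaced k2 values between 0.01 and 3 per minute,
#' covering perfusion 0.1-2 ml/cm^3/min at distribution volumes 0.3-1.2
#' ml/cm^3.
#'
#' @param n Number of grid points.
#' @param k2_min,k2_max Grid bounds (1/min).
#' @return Strictly increasing numeric vector (1/min).
#' @export
default_k2_grid <- function(n = 100, k2_min = 0.01, k2_max = 3) {
  if (k2_min <= 0 || k2_max <= k2_min) {
    abort("Require 0 < k2_min < k2_max.", class = "widif_validation_error")
  }
  exp(seq(log(k2_min), log(k2_max), length.out = n))
}

#' Precompute single-tissue basis functions
#'
#' For each clearance rate on the grid, the basis curve
#' \eqn{B_i(t) = \int_0^t C_a(s) e^{-k_{2,i}(t-s)} ds} is evaluated by exact
#' piecewise-linear convolution on a fine (0.25 s) grid and then averaged
#' over the frame intervals. A tissue TAC is then modelled as
#' \eqn{C_T = F B_i} with F the only linear parameter.
#'
#' @param input Arterial input curve sampled densely (about 1 s or finer)
#'   over the schedule span.
#' @param schedule A [frame_schedule()].
#' @param k2_grid Clearance rates (1/min), strictly increasing and positive.
#' @return An object of class `basis_set`: list with `k2_grid` (1/min),
#'   `frame_basis` (frames x grid matrix), `mid_times`, `schedule`, `input`.
#' @export
make_basis <- function(input, schedule, k2_grid = default_k2_grid()) {
  input <- as_pet_curve(input)
  schedule <- as_frame_schedule(schedule)
  if (any(k2_grid <= 0) || is.unsorted(k2_grid, strictly = TRUE)) {
    abort("`k2_grid` must be positive and strictly increasing.",
          class = "widif_validation_error")
  }
  span <- max(schedule$start_s + schedule$duration_s)
  if (max(input$time_s) < span - 1e-9) {
    abort("Input curve does not cover the schedule span.",
          class = "widif_validation_error")
  }
  grid <- seq(0, span, by = 0.25)
  ca <- curve_interp(input, grid, rule = 2)
  if (min(input$time_s) > 0) ca[grid < min(input$time_s)] <- 0
  n_frames <- nrow(schedule)
  frame_basis <- matrix(0, n_frames, length(k2_grid))
  for (j in seq_along(k2_grid)) {
    conv <- exp_convolve(grid, ca, k2_grid[j] / 60)
    frame_basis[, j] <- resample_to_frames(pet_curve(grid, conv),
                                           schedule)$activity_Bq_ml
  }
  structure(list(k2_grid = k2_grid, frame_basis = frame_basis,
                 mid_times = frame_mid_times(schedule), schedule = schedule,
                 input = input),
            class = "basis_set")
}

#' Fit the single-tissue compartment model to a regional TAC
#'
#' Basis-function fit: for every clearance rate k2 on the grid the single
#' linear coefficient F of `C_T = F * B_k2` is solved by weighted least
#' squares, and the grid point with minimal weighted residual sum of squares
#' wins. Only frames with mid-time at or below `fit_window_s` (default
#' 300 s, the first five minutes) enter the fit; weights default to frame
#' durations. Negative fitted F is clamped to zero and flagged.
#'
#' @param tac Tissue TAC sampled at the schedule's frame mid-times.
#' @param basis A [make_basis()] result.
#' @param weights Per-frame weights (full schedule length); default frame
#'   durations.
#' @param fit_window_s Last frame mid-time admitted to the fit (s).
#' @return An object of class `onetcm_fit` with elements `flow`
#'   (ml/cm^3/min), `vd` (ml/cm^3), `k2` (1/min), `rss` (weighted), `n_frames`,
#'   `clamped` (logical), `delay_s` (always 0 here; delay handling lives in
#'   the blood module), `observed` and `fitted` curves.
#' @export
fit_1tcm <- function(tac, basis, weights = NULL, fit_window_s = 300) {
  tac <- as_pet_curve(tac)
  if (!inherits(basis, "basis_set")) {
    abort("`basis` must come from make_basis().", class = "widif_schema_error")
  }
  mid <- basis$mid_times
  if (nrow(tac) != length(mid) || max(abs(tac$time_s - mid)) > 1e-6) {
    abort("TAC must be sampled at the schedule's frame mid-times.",
          class = "widif_validation_error")
  }
  if (all(basis$input$activity_Bq_ml == 0)) {
    abort("Input curve is identically zero.", class = "widif_validation_error")
  }
  use <- which(mid <= fit_window_s)
  if (length(use) < 2) abort("Fewer than two frames inside the fit window.",
                             class = "widif_validation_error")
  w <- weights %||% basis$schedule$duration_s
  if (length(w) != length(mid) || any(w < 0)) {
    abort("`weights` must be non-negative, one per frame.",
          class = "widif_validation_error")
  }
  y <- tac$activity_Bq_ml[use]
  B <- basis$frame_basis[use, , drop = FALSE]
  w <- w[use]
  wy <- w * y
  num <- drop(crossprod(B, wy))          # sum w B y, per k2
  den <- drop(crossprod(B^2, w))         # sum w B^2, per k2
  coef <- ifelse(den > 0, num / den, 0)
  clamped_any <- coef < 0
  coef[clamped_any] <- 0
  rss <- sum(w * y^2) - 2 * coef * num + coef^2 * den
  best <- which.min(rss)
  f_s <- coef[best]                      # ml/cm^3/s
  k2 <- basis$k2_grid[best]              # 1/min
  flow <- f_s * 60
  fitted <- pet_curve(mid, basis$frame_basis[, best] * f_s)
  structure(list(flow = flow,
                 vd = if (flow > 0) flow / k2 else NA_real_,
                 k2 = k2, rss = rss[best], n_frames = length(use),
                 clamped = clamped_any[best] || all(y == 0), delay_s = 0,
                 k2_index = best, rss_profile = rss,
                 observed = tac, fitted = fitted),
            class = "onetcm_fit")
}

#' @export
print.onetcm_fit <- function(x, ...) {
  cat(sprintf("<onetcm_fit> F = %.3f ml/cm^3/min, Vd = %.3f ml/cm^3, k2 = %.3f /min\n",
              x$flow, x$vd, x$k2))
  cat(sprintf("  weighted RSS %.4g over %d frames%s\n", x$rss, x$n_frames,
              if (x$clamped) " (F clamped at 0)" else ""))
  invisible(x)
}

#' @method tidy onetcm_fit
#' @export
tidy.onetcm_fit <- function(x, ...) {
  tibble(term = c("flow", "vd", "k2"),
         estimate = c(x$flow, x$vd, x$k2),
         unit = c("ml/cm^3/min", "ml/cm^3", "1/min"))
}

#' @method glance onetcm_fit
#' @export
glance.onetcm_fit <- function(x, ...) {
  tibble(flow = x$flow, vd = x$vd, k2 = x$k2, rss = x$rss,
         n_frames = x$n_frames, clamped = x$clamped)
}

#' @method autoplot onetcm_fit
#' @export
autoplot.onetcm_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$observed), series = "observed"),
    dplyr::mutate(as_tibble(object$fitted), series = "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$activity_Bq_ml,
                                   colour = .data$series)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$series == "fitted")) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$series == "observed"),
                        size = 0.9) +
    ggplot2::labs(x = "Time (s)", y = "Activity (Bq/ml)", colour = NULL)
}

#' Voxelwise single-tissue compartment fit
#'
#' Applies [fit_1tcm()] to every voxel of a brain mask, reusing one shared
#' basis set; returns parametric maps of perfusion, distribution volume and
#' clearance. Voxels outside the mask are zero.
#'
#' @param image A [dynamic_image()].
#' @param input Dense arterial input curve.
#' @param brain_mask Non-empty [pet_mask()] on the image grid.
#' @param k2_grid Clearance grid (1/min).
#' @param weights Per-frame weights; default frame durations.
#' @param fit_window_s Fit window (s), default 300.
#' @return A list of 3D arrays `flow` (ml/cm^3/min), `vd` (ml/cm^3),
#'   `k2` (1/min), plus the `basis_set` used.
#' @export
fit_1tcm_voxelwise <- function(image, input, brain_mask,
                               k2_grid = default_k2_grid(), weights = NULL,
                               fit_window_s = 300) {
  stopifnot(inherits(image, "dynamic_image"))
  m <- mask_array(brain_mask)
  if (!identical(dim(m), dim(image$data)[1:3])) {
    abort("Mask grid does not match the image.", class = "widif_validation_error")
  }
  if (!any(m)) abort("Mask is empty.", class = "widif_validation_error")
  basis <- make_basis(input, image$schedule, k2_grid)
  mid <- basis$mid_times
  use <- which(mid <= fit_window_s)
  w <- (weights %||% image$schedule$duration_s)[use]
  B <- basis$frame_basis[use, , drop = FALSE]
  n_vox <- sum(m)
  Y <- matrix(0, length(use), n_vox)
  for (i in seq_along(use)) {
    Y[i, ] <- image$data[, , , use[i]][m]
  }
  num <- crossprod(B, w * Y)             # nk x nvox: sum w B y
  den <- drop(crossprod(B^2, w))         # nk
  coef <- num / den
  coef[coef < 0] <- 0
  obj <- coef * num - 0.5 * coef^2 * den # maximise explained (w) sum of squares
  best <- max.col(t(obj), ties.method = "first")
  pick <- cbind(best, seq_len(n_vox))
  f_s <- coef[pick]
  k2v <- basis$k2_grid[best]
  flow_v <- f_s * 60
  vd_v <- ifelse(flow_v > 0, flow_v / k2v, 0)
  d3 <- dim(m)
  flow_map <- array(0, dim = d3); flow_map[m] <- flow_v
  vd_map <- array(0, dim = d3); vd_map[m] <- vd_v
  k2_map <- array(0, dim = d3); k2_map[m] <- ifelse(flow_v > 0, k2v, 0)
  list(flow = flow_map, vd = vd_map, k2 = k2_map, basis = basis)
}

#' Mean of a parametric map over a region
#'
#' @param map 3D array (e.g. a flow map).
#' @param mask Non-empty [pet_mask()] or 3D logical array.
#' @return Scalar unweighted mean over mask voxels.
#' @export
region_mean <- function(map, mask) {
  m <- mask_array(mask)
  if (!identical(dim(m), dim(map))) {
    abort("Mask grid does not match the map.", class = "widif_validation_error")
  }
  if (!any(m)) abort("Mask is empty.", class = "widif_validation_error")
  mean(map[m])
}
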