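#' Peak/tail AUC metrics of an input curve against a reference
#'
#' Summarises input-curve shape fidelity by the area under the curve of the
#' bolus peak (0-60 s), the tail (60-300 s) and their ratio, together with
#' the relative bias of each versus a reference curve,
#' `100 * (test - reference) / reference`.
#'
#' @param test,reference Curves covering at least 0-300 s.
#' @return A one-row tibble: `peak_auc`, `tail_auc`, `peak_tail_ratio` for
#'   the test curve, the same with suffix `_ref`, and `peak_bias_pct`,
#'   `tail_bias_pct`, `ratio_bias_pct`.
#' @export
auc_metrics <- function(test, reference) {
  test <- as_pet_curve(test)
  reference <- as_pet_curve(reference)
  tmin <- max(min(test$time_s), min(reference$time_s))
  peak <- auc(test, tmin, 60); tail_ <- auc(test, 60, 300)
  peak_r <- auc(reference, tmin, 60); tail_r <- auc(reference, 60, 300)
  if (peak_r == 0 || tail_r == 0) {
    abort("Reference AUC is zero.", class = "widif_validation_error")
  }
  ratio <- if (tail_ > 0) peak / tail_ else NA_real_
  ratio_r <- peak_r / tail_r
  tibble(peak_auc = peak, tail_auc = tail_, peak_tail_ratio = ratio,
         peak_auc_ref = peak_r, tail_auc_ref = tail_r,
         peak_tail_ratio_ref = ratio_r,
         peak_bias_pct = 100 * (peak - peak_r) / peak_r,
         tail_bias_pct = 100 * (tail_ - tail_r) / tail_r,
         ratio_bias_pct = 100 * (ratio - ratio_r) / ratio_r)
}

#' Threshold-by-kernel grid search
#'
#' Re-runs segmentation, partial-volume correction and grey-matter CBF
#' estimation for every combination of mask threshold and Gaussian kernel
#' width, recording the relative bias of the resulting IDIF's peak AUC, tail
#' AUC and peak-to-tail ratio against a reference input function, and of the
#' GM CBF against the CBF obtained with the reference input. Defaults scan
#' thresholds 38-46% in 1% steps and kernels 2.0-2.4 mm in 0.1 mm steps.
#'
#' @param image A [dynamic_image()].
#' @param reference_input Reference input curve (dense; e.g. phantom truth
#'   or a conditioned blood-sampler curve).
#' @param config A [segmentation_config()]; its `threshold_pct` is
#'   overridden cell by cell.
#' @param thresholds Threshold percentages to scan.
#' @param kernels Kernel FWHMs (mm) to scan.
#' @param gm_mask Grey-matter [pet_mask()] for the CBF column.
#' @param sleeve_inner,sleeve_outer Sleeve dilation steps (default 8 and 10).
#' @param k2_grid Clearance grid for the CBF fits.
#' @return A tibble of class `grid_search_result`: one row per cell with
#'   columns `threshold_pct`, `kernel_fwhm_mm`, `peak_bias_pct`,
#'   `tail_bias_pct`, `ratio_bias_pct`, `gm_cbf_bias_pct`, `alpha`, `beta`,
#'   `mask_voxels`. Cells whose mask comes out empty are NaN-filled.
#' @export
grid_search <- function(image, reference_input, config,
                        thresholds = 38:46,
                        kernels = seq(2.0, 2.4, by = 0.1),
                        gm_mask = NULL,
                        sleeve_inner = 8, sleeve_outer = 10,
                        k2_grid = default_k2_grid()) {
  stopifnot(inherits(image, "dynamic_image"),
            inherits(config, "segmentation_config"))
  reference_input <- as_pet_curve(reference_input)
  gm_tac <- NULL
  cbf_ref <- NA_real_
  if (!is.null(gm_mask)) {
    gm_tac <- extract_tac(image, gm_mask)
    basis_ref <- make_basis(reference_input, image$schedule, k2_grid)
    cbf_ref <- fit_1tcm(gm_tac, basis_ref)$flow
  }
  avg <- average_frames(image, config$early_frames)
  cells <- expand.grid(threshold_pct = thresholds, kernel_fwhm_mm = kernels,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::pmap(cells, function(threshold_pct, kernel_fwhm_mm) {
    out <- list(threshold_pct = threshold_pct,
                kernel_fwhm_mm = kernel_fwhm_mm,
                peak_bias_pct = NaN, tail_bias_pct = NaN,
                ratio_bias_pct = NaN, gm_cbf_bias_pct = NaN,
                alpha = NaN, beta = NaN, mask_voxels = 0L)
    tryCatch({
      mask <- threshold_carotid_mask(avg, config$voi, threshold_pct,
                                     image$voxel_size_mm)
      factors <- compute_pvc_factors(mask, kernel_fwhm_mm)
      sleeve <- sleeve_tissue_mask(mask, sleeve_inner, sleeve_outer)
      idif <- correct_blood_curve(extract_tac(image, mask),
                                  extract_tac(image, sleeve), factors)
      met <- auc_metrics(idif, resample_to_frames(reference_input,
                                                  image$schedule))
      out$peak_bias_pct <- met$peak_bias_pct
      out$tail_bias_pct <- met$tail_bias_pct
      out$ratio_bias_pct <- met$ratio_bias_pct
      out$alpha <- factors$alpha
      out$beta <- factors$beta
      out$mask_voxels <- sum(mask$data)
      if (!is.null(gm_tac)) {
        span <- max(image$schedule$start_s + image$schedule$duration_s)
        n_id <- nrow(idif)
        # anchor at zero and hold the last value to the schedule end so the
        # basis covers the full span (only frames <= 300 s enter the fit)
        idif_dense <- pet_curve(c(0, idif$time_s, span),
                                c(0, idif$activity_Bq_ml,
                                  idif$activity_Bq_ml[n_id]))
        basis <- make_basis(idif_dense, image$schedule, k2_grid)
        cbf <- fit_1tcm(gm_tac, basis)$flow
        out$gm_cbf_bias_pct <- 100 * (cbf - cbf_ref) / cbf_ref
      }
      out
    }, error = function(e) out)
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("grid_search_result", class(res))
  res
}

#' @method autoplot grid_search_result
#' @export
autoplot.grid_search_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = dplyr::any_of(c("peak_bias_pct", "tail_bias_pct",
                           "ratio_bias_pct", "gm_cbf_bias_pct")),
    names_to = "metric", values_to = "bias_pct")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$kernel_fwhm_mm),
                                     y = factor(.data$threshold_pct),
                                     fill = .data$bias_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$bias_pct)),
                       size = 2.6) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "Kernel FWHM (mm)", y = "Threshold (%)",
                  fill = "Bias (%)")
}

#' Orthogonal (Deming) regression
#'
#' Least-squares line minimising perpendicular distances (error variance
#' ratio fixed at 1).
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A tibble with `slope` and `intercept`.
#' @export
deming_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("Need paired vectors of length >= 3.", class = "widif_validation_error")
  }
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxx == 0 && syy == 0) {
    abort("Zero variance in both variables.", class = "widif_validation_error")
  }
  slope <- if (sxy == 0) {
    if (syy >= sxx) Inf else 0
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  tibble(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences between paired measurements plotted against their pairwise
#' means; in percent mode the differences are `100 * (y - x) / pairwise
#' mean`. Bias is the mean difference and the limits of agreement are
#' `bias +/- 1.96 * SD` (sample SD).
#'
#' @param x,y Paired measurements (length >= 2).
#' @param percent Use percentage differences (default `TRUE`).
#' @return A one-row tibble: `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `n`, `percent`.
#' @export
bland_altman <- function(x, y, percent = TRUE) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("Need paired vectors of length >= 2.", class = "widif_validation_error")
  }
  means <- (x + y) / 2
  if (percent) {
    if (any(means == 0)) abort("Pairwise mean of zero in percent mode.",
                               class = "widif_validation_error")
    diffs <- 100 * (y - x) / means
  } else {
    diffs <- y - x
  }
  bias <- mean(diffs)
  s <- sd(diffs)
  tibble(bias = bias, sd_diff = s,
         loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
         n = length(x), percent = percent)
}

#' Coefficient of variation of paired differences
#'
#' Dispersion of the disagreement between two paired measurement series,
#' SD divided by mean. The default convention takes the SD of the pairwise
#' percentage differences (`100 * (y - x) / pairwise mean`), which is
#' already mean-normalised; `absolute = TRUE` instead divides the SD of the
#' raw differences by the grand mean of all measurements.
#'
#' @param x,y Paired measurements (length >= 2).
#' @param absolute Use the absolute-difference variant.
#' @return CoV in percent.
#' @export
cov_of_differences <- function(x, y, absolute = FALSE) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("Need paired vectors of length >= 2.", class = "widif_validation_error")
  }
  if (absolute) {
    grand <- mean(c(x, y))
    if (grand == 0) abort("Zero grand mean.", class = "widif_validation_error")
    return(100 * sd(y - x) / grand)
  }
  means <- (x + y) / 2
  if (any(means == 0)) abort("Pairwise mean of zero.",
                             class = "widif_validation_error")
  sd(100 * (y - x) / means)
}

#' Agreement summary between two value sets
#'
#' Bundles the comparison statistics used to judge IDIF-against-reference
#' agreement: Pearson R^2, orthogonal-regression slope and intercept,
#' Bland-Altman bias and limits of agreement (percent), SD of raw
#' differences and the CoV of differences.
#'
#' @param x Reference values (e.g. blood-sampler based CBF).
#' @param y Test values (e.g. image-derived CBF).
#' @return A one-row tibble of class `agreement_stats`.
#' @export
agreement_stats <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("Need paired vectors of length >= 3.", class = "widif_validation_error")
  }
  dem <- deming_regression(x, y)
  ba <- bland_altman(x, y, percent = TRUE)
  out <- tibble(r_squared = stats::cor(x, y)^2,
                slope = dem$slope, intercept = dem$intercept,
                bias_pct = ba$bias, loa_lower_pct = ba$loa_lower,
                loa_upper_pct = ba$loa_upper,
                sd_differences = sd(y - x),
                cov_pct = cov_of_differences(x, y), n = length(x))
  class(out) <- c("agreement_stats", class(out))
  out
}

#' @method glance agreement_stats
#' @export
glance.agreement_stats <- function(x, ...) as_tibble(x)
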