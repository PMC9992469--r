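test_that("trapezoidal AUC is exact on polynomials of degree one and additive", {
  const <- pet_curve(c(0, 30, 60), c(1, 1, 1))
  expect_equal(auc(const, 0, 60), 60)
  ramp <- pet_curve(c(0, 10), c(0, 10))
  expect_equal(auc(ramp, 0, 10), 50)
  withr::local_seed(4)
  crv <- pet_curve(seq(0, 300, by = 7.5), rexp(41, 0.1))
  expect_equal(auc(crv, 0, 60) + auc(crv, 60, 300), auc(crv, 0, 300),
               tolerance = 1e-9)
  expect_equal(auc(crv, 13, 17),
               auc(crv, 13, 15) + auc(crv, 15, 17), tolerance = 1e-9)
  expect_error(auc(crv, 60, 60), class = "widif_validation_error")
  expect_error(auc(crv, 0, 400), class = "widif_validation_error")
})

test_that("AUC metrics report biases relative to the reference", {
  tt <- seq(0, 300, by = 2.5)
  ref <- model_input_function(input_function_model(), tt)
  same <- auc_metrics(ref, ref)
  expect_equal(same$peak_bias_pct, 0)
  expect_equal(same$tail_bias_pct, 0)
  expect_equal(same$ratio_bias_pct, 0)
  up <- pet_curve(tt, ref$activity_Bq_ml * 1.05)
  m <- auc_metrics(up, ref)
  expect_equal(m$peak_bias_pct, 5, tolerance = 1e-9)
  expect_equal(m$tail_bias_pct, 5, tolerance = 1e-9)
  expect_equal(m$ratio_bias_pct, 0, tolerance = 1e-9)
  zero <- pet_curve(tt, rep(0, length(tt)))
  expect_error(auc_metrics(ref, zero), class = "widif_validation_error")
})

test_that("Deming regression recovers exact lines and is slope-symmetric", {
  x <- c(1, 2, 3, 4, 5)
  d1 <- deming_regression(x, x)
  expect_equal(d1$slope, 1); expect_equal(d1$intercept, 0)
  d2 <- deming_regression(x, 2 * x)
  expect_equal(d2$slope, 2); expect_equal(d2$intercept, 0)
  withr::local_seed(8)
  xr <- rnorm(20); yr <- 1.4 * xr + rnorm(20, sd = 0.3)
  xc <- xr - mean(xr); yc <- yr - mean(yr)
  expect_equal(deming_regression(xc, yc)$slope,
               1 / deming_regression(yc, xc)$slope, tolerance = 1e-9)
  expect_error(deming_regression(rep(1, 5), rep(2, 5)),
               class = "widif_validation_error")
})

test_that("Bland-Altman bias and limits follow the construction", {
  x <- c(10, 12, 14, 16)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0); expect_equal(same$sd_diff, 0)
  expect_equal(same$loa_lower, 0); expect_equal(same$loa_upper, 0)
  off <- bland_altman(x, x + 3, percent = FALSE)
  expect_equal(off$bias, 3); expect_equal(off$sd_diff, 0)
  withr::local_seed(12)
  y <- x * (1 + rnorm(4, sd = 0.05))
  ba <- bland_altman(x, y)
  expect_equal(ba$loa_upper - ba$bias, 1.96 * ba$sd_diff)
  expect_equal(ba$bias - ba$loa_lower, 1.96 * ba$sd_diff)
  expect_error(bland_altman(c(1, -1), c(-1, 1)), class = "widif_validation_error")
})

test_that("CoV of differences matches a hand-computed value and is scale-free", {
  x <- c(100, 100)
  y <- c(102, 98)
  # percentage differences: 100*2/101 and 100*(-2)/99; sample SD of those
  hand <- sd(c(200 / 101, -200 / 99))
  expect_equal(cov_of_differences(x, y), hand)
  expect_equal(cov_of_differences(x, x), 0)
  expect_equal(cov_of_differences(7 * x, 7 * y), cov_of_differences(x, y))
  # absolute variant: SD of raw differences over the grand mean
  expect_equal(cov_of_differences(x, y, absolute = TRUE),
               100 * sd(c(2, -2)) / 100)
})

test_that("agreement_stats bundles correlation, regression and Bland-Altman", {
  withr::local_seed(21)
  x <- seq(0.4, 0.9, length.out = 10)
  y <- x * 0.98 + rnorm(10, sd = 0.01)
  st <- agreement_stats(x, y)
  expect_equal(st$r_squared, stats::cor(x, y)^2)
  expect_gt(st$r_squared, 0.9)
  expect_equal(st$slope, deming_regression(x, y)$slope)
  expect_equal(st$cov_pct, cov_of_differences(x, y))
  expect_equal(nrow(glance(st)), 1)
})

test_that("the threshold-by-kernel grid search populates every cell coherently", {
  ph <- small_phantom()
  tr <- ph$truth
  voi <- voi_from_mask(tr$carotid_mask, margin = c(8, 8, 0))
  cfg <- segmentation_config(3:6, 42, voi)
  gs <- grid_search(ph$image, tr$input, cfg, thresholds = c(40, 42, 44),
                    kernels = c(1.9, 2.1, 2.3), gm_mask = tr$gm_mask)
  expect_equal(nrow(gs), 9)
  expect_true(all(is.finite(gs$peak_bias_pct)))
  expect_true(all(is.finite(gs$gm_cbf_bias_pct)))
  expect_true(all(gs$mask_voxels > 0))
  # smooth variation: neighbouring cells differ by < 5 percentage points
  for (metric in c("peak_bias_pct", "tail_bias_pct", "gm_cbf_bias_pct")) {
    tab <- matrix(gs[[metric]], nrow = 3) # thresholds x kernels
    expect_lt(max(abs(diff(tab))), 5)       # across thresholds
    expect_lt(max(abs(t(diff(t(tab))))), 5) # across kernels
  }
  # the matched kernel (the simulation PSF is 2.1 mm) minimises |GM CBF bias|
  by_kernel <- vapply(split(abs(gs$gm_cbf_bias_pct), gs$kernel_fwhm_mm),
                      mean, numeric(1))
  expect_equal(names(which.min(by_kernel)), "2.1")
})

test_that("grid search is self-consistent when the reference is its own IDIF", {
  ph <- small_phantom()
  tr <- ph$truth
  voi <- voi_from_mask(tr$carotid_mask, margin = c(8, 8, 0))
  cfg <- segmentation_config(3:6, 42, voi)
  seg <- segment_carotid(ph$image, cfg)
  fct <- compute_pvc_factors(seg$mask, 2.1)
  sleeve <- sleeve_tissue_mask(seg$mask, 8, 10)
  idif <- correct_blood_curve(seg$tac, extract_tac(ph$image, sleeve), fct)
  span <- 655
  ref <- pet_curve(c(0, idif$time_s, span),
                   c(0, idif$activity_Bq_ml, idif$activity_Bq_ml[26]))
  gs <- grid_search(ph$image, ref, cfg, thresholds = 42, kernels = 2.1)
  expect_lt(abs(gs$peak_bias_pct), 1.5)
  expect_lt(abs(gs$tail_bias_pct), 1.5)
})

test_that("uncorrected peak AUC rises monotonically with the threshold", {
  ph <- small_phantom()
  avg <- average_frames(ph$image, 3:6)
  voi <- voi_from_mask(ph$truth$carotid_mask, margin = c(8, 8, 0))
  peaks <- vapply(c(30, 42, 55, 70), function(thr) {
    mask <- threshold_carotid_mask(avg, voi, thr)
    auc(extract_tac(ph$image, mask), 2.5, 60)
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})
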