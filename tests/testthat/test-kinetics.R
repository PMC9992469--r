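dense_input <- function(end = 660) {
  model_input_function(input_function_model(), seq(0, end, by = 0.5))
}

test_that("basis functions behave like exponentials for an impulse input", {
  tt <- seq(0, 660, by = 0.5)
  vals <- numeric(length(tt)); vals[tt <= 1] <- 1 # ~unit-height 1-s pulse
  sched <- frame_schedule(seq(0, 600, by = 60), rep(60, 11))
  k2s <- c(0.1, 0.5, 1)
  basis <- make_basis(pet_curve(tt, vals), sched, k2s)
  for (j in seq_along(k2s)) {
    # after the pulse dies the basis is exactly C exp(-k2 t): consecutive
    # 60-s frame averages shrink by exactly exp(-k2 * 60 s)
    ratios <- basis$frame_basis[3:11, j] / basis$frame_basis[2:10, j]
    expect_equal(ratios, rep(exp(-k2s[j]), 9), tolerance = 1e-9)
  }
  # monotone ordering: larger k2 gives a pointwise smaller basis
  expect_true(all(diff(t(basis$frame_basis)) <= 1e-12))
  expect_error(make_basis(pet_curve(c(0, 100), c(0, 1)), sched, k2s),
               class = "widif_validation_error")
})

test_that("noise-free single-tissue TACs are recovered to high accuracy", {
  inp <- dense_input()
  sched <- default_frame_schedule()
  basis <- make_basis(inp, sched)
  step <- exp(diff(log(default_k2_grid()))[1])
  for (truth in list(c(0.64, 0.9), c(0.2, 0.8), c(1.2, 1.2))) {
    tac <- resample_to_frames(
      tissue_response(inp, truth[1], truth[2], inp$time_s), sched)
    fit <- fit_1tcm(tac, basis)
    expect_lt(abs(fit$flow - truth[1]) / truth[1], 0.02)
    expect_lt(abs(log(fit$vd / truth[2])), log(step) * 1.0001)
  }
})

test_that("the exponential-input closed form is reproduced by the fitted curve", {
  lambda <- 0.005
  tt <- seq(0, 660, by = 0.5)
  ca <- pet_curve(tt, 1e4 * exp(-lambda * tt))
  sched <- default_frame_schedule()
  flow <- 0.6; vd <- 0.9
  tac <- resample_to_frames(tissue_response(ca, flow, vd, tt), sched)
  # grid containing the true k2, so quantisation cannot mask convolution errors
  grid <- sort(unique(c(default_k2_grid(), flow / vd)))
  fit <- fit_1tcm(tac, make_basis(ca, sched, grid))
  expect_equal(fit$k2, flow / vd, tolerance = 1e-9)
  expect_equal(fit$flow, flow, tolerance = 1e-3)
  # fitted frame values match the frame-averaged analytic solution
  k2_s <- flow / vd / 60
  analytic <- pet_curve(tt, (flow / 60) * 1e4 *
                          (exp(-lambda * tt) - exp(-k2_s * tt)) /
                          (k2_s - lambda))
  mids <- frame_mid_times(sched)
  use <- mids <= 300
  expect_equal(fit$fitted$activity_Bq_ml[use],
               resample_to_frames(analytic, sched)$activity_Bq_ml[use],
               tolerance = 1e-3)
})

test_that("degenerate TACs and scaling behave as documented", {
  inp <- dense_input()
  sched <- default_frame_schedule()
  basis <- make_basis(inp, sched)
  zero_tac <- pet_curve(frame_mid_times(sched), rep(0, 26))
  fit0 <- fit_1tcm(zero_tac, basis)
  expect_equal(fit0$flow, 0)
  expect_true(fit0$clamped)
  # scale equivariance: input scaled by c leaves k2, scales F and Vd by 1/c
  tac <- resample_to_frames(tissue_response(inp, 0.64, 0.9, inp$time_s), sched)
  fit1 <- fit_1tcm(tac, basis)
  scaled <- pet_curve(inp$time_s, inp$activity_Bq_ml * 2)
  fit2 <- fit_1tcm(tac, make_basis(scaled, sched))
  expect_equal(fit2$flow, fit1$flow / 2, tolerance = 1e-9)
  expect_equal(fit2$k2, fit1$k2)
  expect_equal(fit2$vd, fit1$vd / 2, tolerance = 1e-9)
})

test_that("the RSS profile over k2 is unimodal for noise-free data", {
  inp <- dense_input()
  sched <- default_frame_schedule()
  basis <- make_basis(inp, sched)
  tac <- resample_to_frames(tissue_response(inp, 0.5, 0.8, inp$time_s), sched)
  fit <- fit_1tcm(tac, basis)
  prof <- fit$rss_profile
  # strictly one sign change in the discrete derivative (down then up)
  drops <- diff(prof) < 0
  expect_equal(rle(drops)$values, c(TRUE, FALSE))
})

test_that("tidy and glance expose the fit in broom style", {
  inp <- dense_input()
  sched <- default_frame_schedule()
  tac <- resample_to_frames(tissue_response(inp, 0.64, 0.9, inp$time_s), sched)
  fit <- fit_1tcm(tac, make_basis(inp, sched))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("flow", "vd", "k2"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("flow", "vd", "k2", "rss", "n_frames") %in% names(gl)))
})

test_that("voxelwise maps agree with regional fits on homogeneous regions", {
  ph <- small_phantom()
  tr <- ph$truth
  # restrict to a manageable sub-mask of interior GM voxels
  gm <- widif:::mask_array(tr$gm_mask)
  interior <- gm & !widif:::mask_array(
    dilate_mask(pet_mask(!gm, ph$image$voxel_size_mm), 2))
  idx <- which(interior)
  keep <- array(FALSE, dim = dim(gm)); keep[idx[seq_len(min(600, length(idx)))]] <- TRUE
  sub_mask <- pet_mask(keep, ph$image$voxel_size_mm)
  maps <- fit_1tcm_voxelwise(ph$image, tr$input, sub_mask)
  f_vox <- maps$flow[keep]
  expect_lt(median(abs(f_vox - 0.64) / 0.64), 0.02)
  # region mean of voxel flows matches the regional fit within 1%
  regional <- fit_1tcm(extract_tac(ph$image, sub_mask),
                       make_basis(tr$input, ph$image$schedule))
  expect_equal(region_mean(maps$flow, sub_mask), regional$flow,
               tolerance = 0.01)
  # all-zero image yields zero maps
  zero_img <- dynamic_image(array(0, dim = dim(ph$image$data)),
                            ph$image$voxel_size_mm, ph$image$schedule)
  zmaps <- fit_1tcm_voxelwise(zero_img, tr$input, sub_mask)
  expect_true(all(zmaps$flow == 0) && all(zmaps$vd == 0))
})

test_that("region_mean is a plain masked mean", {
  vol <- array(2, dim = c(4, 4, 4))
  m <- array(FALSE, dim = c(4, 4, 4)); m[1, 1, 1] <- TRUE
  vol[1, 1, 1] <- 9
  expect_equal(region_mean(vol, pet_mask(m, c(1, 1, 1))), 9)
  all_m <- pet_mask(array(TRUE, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_equal(region_mean(array(5, dim = c(4, 4, 4)), all_m), 5)
  expect_error(region_mean(vol, pet_mask(array(FALSE, dim = c(4, 4, 4)),
                                         c(1, 1, 1))),
               class = "widif_validation_error")
})
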