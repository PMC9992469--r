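test_that("input model is zero before appearance and peak-normalised", {
  mod <- input_function_model(amplitude = 5e4, t0_s = 10, shape = 3,
                              scale_s = 15, tail_fraction = 0)
  crv <- model_input_function(mod, c(0, 5, 10, 25, 60))
  expect_equal(crv$activity_Bq_ml[1:3], c(0, 0, 0))
  expect_equal(crv$activity_Bq_ml[4], 5e4) # exactly A at the peak, t0 + scale
  # the peak really is the maximum
  dense <- model_input_function(mod, seq(0, 120, by = 0.01))
  expect_equal(max(dense$activity_Bq_ml), 5e4, tolerance = 1e-6)
  expect_error(model_input_function(mod, c(-1, 5)),
               class = "widif_validation_error")
})

test_that("input-model AUC agrees with direct quadrature of the analytic form", {
  mod <- input_function_model(amplitude = 1e5, t0_s = 10, shape = 3,
                              scale_s = 15, tail_fraction = 0)
  crv <- model_input_function(mod, seq(0, 300, by = 0.1))
  analytic <- function(t) {
    u <- (t - 10) / 15
    ifelse(u > 0, 1e5 * u^3 * exp(3 * (1 - u)), 0)
  }
  oracle <- integrate(analytic, 0, 300, rel.tol = 1e-9)$value
  expect_equal(auc(crv, 0, 300), oracle, tolerance = 1e-3)
})

test_that("tissue response matches the closed-form exponential-input solution", {
  # C_a = exp(-lambda t)  =>  C_T = F (exp(-lambda t) - exp(-k2 t)) / (k2 - lambda)
  lambda <- 0.01
  flow <- 0.6; vd <- 0.9
  k2 <- (flow / vd) / 60
  tt <- seq(0, 300, by = 0.5)
  ca <- pet_curve(tt, exp(-lambda * tt))
  ct <- tissue_response(ca, flow, vd, tt)
  expected <- (flow / 60) * (exp(-lambda * tt) - exp(-k2 * tt)) / (k2 - lambda)
  expect_equal(ct$activity_Bq_ml[-1], expected[-1], tolerance = 1e-4)
  # zero input gives zero output
  z <- tissue_response(pet_curve(tt, 0 * tt), flow, vd, tt)
  expect_true(all(z$activity_Bq_ml == 0))
})

test_that("tissue response approaches Vd times a constant input", {
  tt <- seq(0, 4000, by = 0.5)
  ct <- tissue_response(pet_curve(tt, rep(100, length(tt))), 0.6, 0.9, tt)
  expect_equal(ct$activity_Bq_ml[length(tt)], 0.9 * 100, tolerance = 1e-3)
})

test_that("dynamic phantom reduces to the frame-averaged truth without PSF or noise", {
  spec <- dynamic_phantom_spec(grid_dim = c(32, 32, 18), psf_fwhm_mm = 0,
                               noise_scale = 0,
                               schedule = frame_schedule(seq(0, 50, 10), rep(10, 6)))
  ph <- generate_dynamic_phantom(spec)
  occ <- ph$truth$carotid_occupancy
  full <- which(occ == 1, arr.ind = TRUE)[1, ] # a fully-inside tube voxel
  series <- ph$image$data[full[1], full[2], full[3], ]
  expect_equal(series, ph$truth$input_frames$activity_Bq_ml, tolerance = 1e-12)
  gm_idx <- which(widif:::mask_array(ph$truth$gm_mask), arr.ind = TRUE)[1, ]
  gm_series <- ph$image$data[gm_idx[1], gm_idx[2], gm_idx[3], ]
  ref <- resample_to_frames(
    tissue_response(ph$truth$input, spec$gm_flow, spec$gm_vd,
                    ph$truth$input$time_s),
    spec$schedule)
  expect_equal(gm_series, ref$activity_Bq_ml, tolerance = 1e-9)
})

test_that("dynamic phantom noise is reproducible from the seed", {
  spec <- dynamic_phantom_spec(grid_dim = c(24, 24, 12),
                               schedule = frame_schedule(seq(0, 50, 10), rep(10, 6)),
                               seed = 42)
  a <- generate_dynamic_phantom(spec)
  b <- generate_dynamic_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  spec2 <- dynamic_phantom_spec(grid_dim = c(24, 24, 12),
                                schedule = frame_schedule(seq(0, 50, 10), rep(10, 6)),
                                seed = 43)
  expect_false(identical(generate_dynamic_phantom(spec2)$image$data, a$image$data))
})

test_that("blurring conserves total activity for interior objects and commutes with frame averaging", {
  withr::local_seed(5)
  arr <- array(0, dim = c(20, 20, 14, 3))
  arr[8:12, 9:13, 6:9, ] <- rexp(5 * 5 * 4 * 3, rate = 1e-4)
  vox <- scanner_voxels
  for (f in 1:3) {
    sm <- gaussian_smooth(arr[, , , f], 2.3, vox)
    expect_equal(sum(sm), sum(arr[, , , f]), tolerance = 1e-6)
  }
  avg_then_blur <- gaussian_smooth((arr[, , , 1] + arr[, , , 2] + arr[, , , 3]) / 3,
                                   2.3, vox)
  blur_then_avg <- (gaussian_smooth(arr[, , , 1], 2.3, vox) +
                      gaussian_smooth(arr[, , , 2], 2.3, vox) +
                      gaussian_smooth(arr[, , , 3], 2.3, vox)) / 3
  expect_equal(avg_then_blur, blur_then_avg, tolerance = 1e-9)
})

test_that("static tube phantom carries the nominal concentration and blurs plausibly", {
  ph <- static_phantom()
  occ <- ph$truth$tube_occupancy
  # total activity equals concentration times analytic cross-section
  vox_area <- scanner_voxels[1] * scanner_voxels[2]
  # 4x in-plane supersampling quantises occupancy in 1/16 steps
  expect_equal(sum(occ[, , 1]) * vox_area, pi * 3^2, tolerance = 0.01)
  # fully-interior voxels carry exactly the nominal concentration pre-blur
  sp0 <- static_phantom_spec(psf_fwhm_mm = 0)
  ph0 <- generate_static_tube_phantom(sp0)
  expect_equal(mean(ph0$image[ph0$truth$tube_occupancy == 1]), 2.1e6)
  # smoothing a compact hot object lowers its maximum
  expect_lt(max(ph$image), 2.1e6)
})

test_that("sub-resolution tubes trigger a warning", {
  expect_warning(
    generate_dynamic_phantom(
      dynamic_phantom_spec(grid_dim = c(24, 24, 12), tube_diameter_mm = 1.5,
                           noise_scale = 0,
                           schedule = frame_schedule(c(0, 10), c(10, 10)))),
    "Sub-resolution|sub-resolution")
})
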