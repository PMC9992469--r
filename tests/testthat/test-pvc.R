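test_that("Gaussian smoothing preserves constants and has exact identity cases", {
  vol <- array(7.5, dim = c(10, 10, 8))
  expect_equal(gaussian_smooth(vol, 2.4, scanner_voxels), vol, tolerance = 1e-12)
  withr::local_seed(1)
  noise <- array(rnorm(10 * 10 * 8), dim = c(10, 10, 8))
  expect_identical(gaussian_smooth(noise, 0, scanner_voxels), noise)
  expect_error(gaussian_smooth(noise, -1, scanner_voxels),
               class = "widif_validation_error")
})

test_that("impulse response equals the explicit normalised kernel", {
  vol <- array(0, dim = c(11, 11, 11))
  vol[6, 6, 6] <- 1
  sm <- gaussian_smooth(vol, 2 * sqrt(2 * log(2)), c(1, 1, 1)) # sigma = 1 voxel
  # oracle: construct the truncated normalised 1D kernel and take the
  # centre coefficient of its separable 3D product
  r <- ceiling(4)
  k1 <- exp(-((-r):r)^2 / 2); k1 <- k1 / sum(k1)
  expect_equal(sm[6, 6, 6], k1[r + 1]^3, tolerance = 1e-12)
  expect_equal(sm[6, 6, 7], k1[r + 1]^2 * k1[r + 2], tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
})

test_that("spill-out and spill-in have the exact limiting values", {
  ones <- pet_mask(array(TRUE, dim = c(6, 6, 4)), scanner_voxels)
  expect_equal(spillout_alpha(ones, 2.1), 1, tolerance = 1e-12)
  expect_equal(spillin_beta(ones, 2.1), 0, tolerance = 1e-12)
  m <- array(FALSE, dim = c(12, 12, 8)); m[5:7, 5:7, 3:5] <- TRUE
  msk <- pet_mask(m, scanner_voxels)
  expect_equal(spillout_alpha(msk, 0), 1)
  expect_equal(spillin_beta(msk, 0), 0)
  expect_error(spillout_alpha(pet_mask(array(FALSE, dim = c(4, 4, 4)),
                                       scanner_voxels), 2.1),
               class = "widif_validation_error")
})

test_that("alpha matches a brute-force dense convolution oracle", {
  # tube-like mask on the scanner grid
  m <- array(FALSE, dim = c(24, 24, 14))
  for (z in 3:12) m[10:15, 11:14, z] <- TRUE
  msk <- pet_mask(m, scanner_voxels)
  idx <- which(m, arr.ind = TRUE)
  vol <- array(as.numeric(m), dim = dim(m))
  oracle <- mean(dense_smooth_at(vol, 2.1, scanner_voxels, idx))
  expect_equal(spillout_alpha(msk, 2.1), oracle, tolerance = 1e-6)
})

test_that("alpha + beta = 1 and alpha decreases with kernel width", {
  withr::local_seed(9)
  msk <- random_interior_mask()
  alphas <- vapply(c(0.5, 1, 2.1, 3, 5),
                   function(f) spillout_alpha(msk, f), numeric(1))
  betas <- vapply(c(0.5, 1, 2.1, 3, 5),
                  function(f) spillin_beta(msk, f), numeric(1))
  expect_equal(alphas + betas, rep(1, 5), tolerance = 1e-6)
  expect_true(all(diff(alphas) < 0))
  expect_gt(alphas[1], 0.9) # alpha -> 1 as the kernel shrinks
})

test_that("sleeve mask is the outer minus inner dilation shell", {
  m <- array(FALSE, dim = c(9, 9, 9)); m[5, 5, 5] <- TRUE
  msk <- pet_mask(m, c(1, 1, 1))
  sleeve <- sleeve_tissue_mask(msk, inner = 1, outer = 2)
  # L1 ball of radius 2 minus radius 1: 25 - 7 = 18 voxels
  expect_equal(sum(sleeve$data), 18)
  inner <- dilate_mask(msk, 1)
  expect_false(any(sleeve$data & inner$data))
  expect_false(any(sleeve$data & msk$data))
  expect_error(sleeve_tissue_mask(msk, inner = 2, outer = 2),
               class = "widif_validation_error")
  expect_error(sleeve_tissue_mask(pet_mask(array(FALSE, dim = c(3, 3, 3)),
                                           c(1, 1, 1)), 1, 2),
               class = "widif_validation_error")
})

test_that("dilation connectivity changes the unit ball as expected", {
  m <- array(FALSE, dim = c(7, 7, 7)); m[4, 4, 4] <- TRUE
  msk <- pet_mask(m, c(1, 1, 1))
  expect_equal(sum(dilate_mask(msk, 1, 6)$data), 7)
  expect_equal(sum(dilate_mask(msk, 1, 18)$data), 19)
  expect_equal(sum(dilate_mask(msk, 1, 26)$data), 27)
})

test_that("blood-curve correction applies the spill equation pointwise", {
  tt <- c(5, 15, 25)
  carotid <- pet_curve(tt, c(0.6, 0.6, 0.6))
  tissue <- pet_curve(tt, c(0.2, 0.2, 0.2))
  out <- correct_blood_curve(carotid, tissue, pvc_factors(0.5, 0.5, 2.1))
  expect_equal(out$activity_Bq_ml, rep((0.6 - 0.1) / 0.5, 3)) # = 1.0
  ident <- correct_blood_curve(carotid, tissue, pvc_factors(1, 0, 2.1))
  expect_equal(ident$activity_Bq_ml, carotid$activity_Bq_ml)
  expect_error(correct_blood_curve(carotid, pet_curve(tt + 1, c(0, 0, 0)),
                                   pvc_factors(0.5, 0.5, 2.1)),
               class = "widif_validation_error")
  expect_error(pvc_factors(0, 0.5, 2.1), class = "widif_validation_error")
})

test_that("correction exactly recovers the blood curve on a blur-consistent image", {
  vox <- scanner_voxels
  m <- array(FALSE, dim = c(40, 40, 24)); m[18:22, 19:23, 8:16] <- TRUE
  msk <- pet_mask(m, vox)
  fwhm <- 2.1
  sm <- gaussian_smooth(array(as.numeric(m), dim = dim(m)), fwhm, vox)
  sminv <- gaussian_smooth(array(as.numeric(!m), dim = dim(m)), fwhm, vox)
  sched <- frame_schedule(seq(0, 50, by = 10), rep(10, 6))
  cb <- c(0, 5e4, 8e4, 4e4, 2e4, 1e4)
  ct <- c(0, 1e3, 5e3, 8e3, 9e3, 9e3)
  arr <- array(0, dim = c(dim(m), 6))
  for (f in 1:6) arr[, , , f] <- cb[f] * sm + ct[f] * sminv
  img <- dynamic_image(arr, vox, sched)
  factors <- compute_pvc_factors(msk, fwhm)
  sleeve <- sleeve_tissue_mask(msk, 8, 10)
  idif <- correct_blood_curve(extract_tac(img, msk), extract_tac(img, sleeve),
                              factors)
  expect_equal(idif$activity_Bq_ml, cb, tolerance = 1e-6)
})
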