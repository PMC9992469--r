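#' Separable Gaussian smoothing of a volume
#'
#' Smooths a 3D (or framewise a 4D) volume with a separable Gaussian of the
#' given full width at half maximum. The per-axis standard deviation in
#' voxels is `(fwhm_mm / 2.3548) / voxel_size_mm`; the discrete kernel is
#' truncated at 4 sigma and renormalised, and the boundary is replicated so
#' constants are preserved exactly (which is what makes the spill-out and
#' spill-in factors sum to one). `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D or 4D numeric array.
#' @param fwhm_mm Kernel FWHM in mm (scalar, >= 0).
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return Array of the same shape.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1 || !is.finite(fwhm_mm) ||
      fwhm_mm < 0) {
    abort("`fwhm_mm` must be a single non-negative number.",
          class = "widif_validation_error")
  }
  nd <- length(dim(volume))
  if (!nd %in% c(3, 4)) abort("`volume` must be 3D or 4D.", class = "widif_shape_error")
  if (fwhm_mm == 0) return(volume)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (nd == 4) {
    out <- volume
    for (f in seq_len(dim(volume)[4])) {
      out[, , , f] <- gaussian_smooth(volume[, , , f], fwhm_mm, voxel_size_mm)
    }
    return(out)
  }
  sigma_vox <- (fwhm_mm / FWHM_TO_SIGMA) / voxel_size_mm
  out <- volume
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[axis])
    if (length(k) > 1) out <- convolve_axis_replicate(out, k, axis)
  }
  out
}

FWHM_TO_SIGMA <- 2 * sqrt(2 * log(2)) # 2.3548

# Normalised discrete Gaussian, truncated at 4 sigma (at least radius 1 when
# sigma > 0 but sub-voxel).
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along one axis of a 3D array with replicate (edge-clamped)
# boundary; kernel length must be odd.
convolve_axis_replicate <- function(x, kernel, axis) {
  n <- dim(x)[axis]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = dim(x))
  base <- seq_len(n)
  for (j in seq_along(kernel)) {
    idx <- pmin(pmax(base + (j - r - 1L), 1L), n)
    shifted <- switch(axis,
                      x[idx, , , drop = FALSE],
                      x[, idx, , drop = FALSE],
                      x[, , idx, drop = FALSE])
    out <- out + kernel[j] * shifted
  }
  out
}

#' Spill-out and spill-in factors for a carotid mask
#'
#' The spill-out factor `alpha` is the fraction of true in-mask signal that
#' remains inside the mask after blurring with the resolution kernel:
#' `alpha = sum(smooth(mask) * mask) / sum(mask)`. The spill-in factor
#' `beta` is the fraction of the in-mask measurement contributed by
#' surroundings at unit concentration:
#' `beta = sum(smooth(1 - mask) * mask) / sum(mask)`. With the
#' constant-preserving boundary used here, `alpha + beta = 1` for any mask.
#'
#' @param mask A [pet_mask()] (non-empty).
#' @param fwhm_mm Gaussian kernel FWHM in mm.
#' @return Scalar factor.
#' @export
spillout_alpha <- function(mask, fwhm_mm) {
  if (!inherits(mask, "pet_mask")) {
    abort("`mask` must be a pet_mask.", class = "widif_schema_error")
  }
  m <- mask_array(mask)
  if (!any(m)) abort("Mask is empty.", class = "widif_validation_error")
  sm <- gaussian_smooth(array(as.numeric(m), dim = dim(m)), fwhm_mm,
                        mask$voxel_size_mm)
  sum(sm[m]) / sum(m)
}

#' @rdname spillout_alpha
#' @export
spillin_beta <- function(mask, fwhm_mm) {
  if (!inherits(mask, "pet_mask")) {
    abort("`mask` must be a pet_mask.", class = "widif_schema_error")
  }
  m <- mask_array(mask)
  if (!any(m)) abort("Mask is empty.", class = "widif_validation_error")
  sm <- gaussian_smooth(array(as.numeric(!m), dim = dim(m)), fwhm_mm,
                        mask$voxel_size_mm)
  sum(sm[m]) / sum(m)
}

#' Partial-volume correction factors
#'
#' @param alpha Spill-out factor, in (0, 1].
#' @param beta Spill-in factor, in [0, 1).
#' @param kernel_fwhm_mm FWHM of the Gaussian kernel that produced them.
#' @return An object of class `pvc_factors`.
#' @export
pvc_factors <- function(alpha, beta, kernel_fwhm_mm) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1 + 1e-9) {
    abort("`alpha` must lie in (0, 1].", class = "widif_validation_error")
  }
  if (!is.finite(beta) || beta < 0 || beta >= 1) {
    abort("`beta` must lie in [0, 1).", class = "widif_validation_error")
  }
  structure(list(alpha = alpha, beta = beta, kernel_fwhm_mm = kernel_fwhm_mm),
            class = "pvc_factors")
}

#' @export
print.pvc_factors <- function(x, ...) {
  cat(sprintf("<pvc_factors> alpha = %.4f, beta = %.4f (kernel %.2f mm FWHM)\n",
              x$alpha, x$beta, x$kernel_fwhm_mm))
  invisible(x)
}

#' Compute both PVC factors for a mask
#'
#' @inheritParams spillout_alpha
#' @return A [pvc_factors()] object.
#' @export
compute_pvc_factors <- function(mask, fwhm_mm) {
  pvc_factors(spillout_alpha(mask, fwhm_mm), spillin_beta(mask, fwhm_mm),
              fwhm_mm)
}

# One 6/18/26-connected binary dilation step (union of shifted copies,
# voxels pushed outside the grid are dropped).
dilate_once <- function(m, connectivity = 6) {
  d <- dim(m)
  offsets <- switch(as.character(connectivity),
    "6" = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)),
    "18" = { o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
             o[rowSums(abs(o)) %in% c(1, 2), , drop = FALSE] },
    "26" = { o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
             o[rowSums(abs(o)) > 0, , drop = FALSE] },
    abort("`connectivity` must be 6, 18 or 26.", class = "widif_validation_error"))
  out <- m
  for (i in seq_len(nrow(offsets))) {
    out <- out | shift_mask(m, offsets[i, ])
  }
  out
}

# Shift a logical 3D array by an integer offset, filling with FALSE.
shift_mask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { dst[[a]] <- seq_len(d[a] - o) + o; src[[a]] <- seq_len(d[a] - o) }
    else        { dst[[a]] <- seq_len(d[a] + o);     src[[a]] <- seq_len(d[a] + o) - o }
    if (!length(dst[[a]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Iterated binary dilation
#'
#' @param mask A [pet_mask()].
#' @param iterations Number of unit dilation steps (>= 0).
#' @param connectivity 6 (face), 18 (face+edge) or 26 (full) neighbourhood.
#' @return A [pet_mask()].
#' @export
dilate_mask <- function(mask, iterations, connectivity = 6) {
  m <- mask_array(mask)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0) {
    abort("`iterations` must be a non-negative integer.",
          class = "widif_validation_error")
  }
  for (i in seq_len(iterations)) m <- dilate_once(m, connectivity)
  pet_mask(m, mask$voxel_size_mm)
}

#' Sleeve mask of surrounding tissue
#'
#' Shell around the carotid used to sample the surrounding-tissue TAC: the
#' `outer`-step dilation of the carotid mask minus its `inner`-step dilation
#' (defaults 10 and 8 unit dilations, i.e. the 8-voxel dilation subtracted
#' from the 10-voxel dilation). The shell is far enough out to escape
#' carotid spill-over yet stays in the neck. Dilation counts voxel steps, so
#' the shell is anisotropic in mm on anisotropic grids.
#'
#' @param mask Non-empty carotid [pet_mask()].
#' @param inner,outer Dilation step counts, `outer > inner >= 1`.
#' @param connectivity Neighbourhood for the unit dilation (default 6).
#' @return A [pet_mask()] disjoint from the inner dilation.
#' @export
sleeve_tissue_mask <- function(mask, inner = 8, outer = 10, connectivity = 6) {
  if (!(outer > inner && inner >= 1)) {
    abort("Require `outer > inner >= 1`.", class = "widif_validation_error")
  }
  m <- mask_array(mask)
  if (!any(m)) abort("Mask is empty.", class = "widif_validation_error")
  inner_m <- mask_array(dilate_mask(mask, inner, connectivity))
  outer_m <- inner_m
  for (i in seq_len(outer - inner)) outer_m <- dilate_once(outer_m, connectivity)
  sleeve <- outer_m & !inner_m
  if (!any(sleeve)) {
    abort("Sleeve is empty (mask fills the grid).", class = "widif_validation_error")
  }
  pet_mask(sleeve, mask$voxel_size_mm)
}

#' Partial-volume-corrected blood curve
#'
#' Applies the geometric correction
#' `C_B(t) = (C_B_PET(t) - beta * C_T(t)) / alpha`, where `C_B_PET` is the
#' uncorrected carotid-mask TAC and `C_T` the surrounding-tissue (sleeve)
#' TAC. Negative outputs are permitted (noise) but a warning is issued when
#' the corrected curve's AUC over 0-60 s is negative.
#'
#' @param carotid_tac,tissue_tac Curves on identical time grids.
#' @param factors A [pvc_factors()] object.
#' @return A [pet_curve()]: the corrected blood curve.
#' @export
correct_blood_curve <- function(carotid_tac, tissue_tac, factors) {
  carotid_tac <- as_pet_curve(carotid_tac)
  tissue_tac <- as_pet_curve(tissue_tac)
  if (!inherits(factors, "pvc_factors")) {
    abort("`factors` must be a pvc_factors object.", class = "widif_schema_error")
  }
  if (nrow(carotid_tac) != nrow(tissue_tac) ||
      max(abs(carotid_tac$time_s - tissue_tac$time_s)) > 1e-6) {
    abort("Carotid and tissue TACs must share one time grid.",
          class = "widif_validation_error")
  }
  if (factors$alpha <= 0) {
    abort("`alpha` must be positive.", class = "widif_validation_error")
  }
  corrected <- (carotid_tac$activity_Bq_ml -
                  factors$beta * tissue_tac$activity_Bq_ml) / factors$alpha
  out <- pet_curve(carotid_tac$time_s, corrected)
  if (max(out$time_s) >= 60 && auc(out, min(out$time_s), 60) < 0) {
    warn("Corrected blood curve has negative AUC over the first minute.")
  }
  out
}
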