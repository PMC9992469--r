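#' Crop a scan to the neck region
#'
#' Restricts the image to the bottom (inferior) third of the axial
#' field-of-view, where the carotid arteries run and most of the brain is
#' excluded. Requires the canonical orientation (inferior at axial index 1).
#'
#' @param image A [dynamic_image()] with at least 3 axial slices.
#' @return A list with `image` (the cropped [dynamic_image()]) and `voi`
#'   (the [voi_box()] of the crop in the original grid).
#' @export
crop_neck <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$data)
  if (d[3] < 3) abort("Need at least 3 axial slices to take the bottom third.",
                      class = "widif_validation_error")
  nz <- floor(d[3] / 3)
  voi <- voi_box(1, d[1], 1, d[2], 1, nz)
  cropped <- dynamic_image(image$data[, , seq_len(nz), , drop = FALSE],
                           image$voxel_size_mm, image$schedule)
  list(image = cropped, voi = voi)
}

#' Advisory early-frame suggestion
#'
#' Frame selection for carotid segmentation is a manual step (the carotids
#' must be visibly filled with tracer while the brain is still empty); this
#' heuristic is a documented convenience only. Among frames `1..max_frame`
#' it returns the contiguous run of frames whose within-neck maximum exceeds
#' 20% of the largest within-neck maximum over those frames, restricted to
#' frames before the whole-image activity peak (when tracer floods the
#' brain).
#'
#' @param image A [dynamic_image()].
#' @param max_frame Last candidate frame (default 6, the first 30 s of the
#'   standard schedule).
#' @return Integer frame indices (possibly empty, with a warning).
#' @export
suggest_early_frames <- function(image, max_frame = 6) {
  stopifnot(inherits(image, "dynamic_image"))
  n_frames <- dim(image$data)[4]
  max_frame <- min(as.integer(max_frame), n_frames)
  neck <- crop_neck(image)$image
  cand <- seq_len(max_frame)
  neck_max <- vapply(cand, function(f) max(neck$data[, , , f]), numeric(1))
  totals <- vapply(seq_len(n_frames), function(f) sum(image$data[, , , f]),
                   numeric(1))
  peak_frame <- which.max(totals)
  ok <- neck_max > 0.2 * max(neck_max) & cand < peak_frame
  if (!any(ok)) {
    warn("No qualifying early frame found; supply frame indices manually.")
    return(integer(0))
  }
  # longest contiguous qualifying run
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  good <- which(runs$values)
  best <- good[which.max(runs$lengths[good])]
  seq(starts[best], ends[best])
}

#' Average selected frames
#'
#' Unweighted voxelwise mean of the chosen early frames (the early frames of
#' the standard schedule all last 5 s, so this equals duration weighting
#' there).
#'
#' @param image A [dynamic_image()].
#' @param indices Non-empty vector of distinct 1-based frame indices.
#' @return A 3D array with a `voxel_size_mm` attribute.
#' @export
average_frames <- function(image, indices) {
  stopifnot(inherits(image, "dynamic_image"))
  indices <- as.integer(indices)
  if (!length(indices)) abort("`indices` must be non-empty.",
                              class = "widif_validation_error")
  if (anyDuplicated(indices)) abort("Duplicate frame indices.",
                                    class = "widif_validation_error")
  if (any(indices < 1 | indices > dim(image$data)[4])) {
    abort("Frame index out of range.", class = "widif_validation_error")
  }
  d <- dim(image$data)[1:3]
  out <- array(0, dim = d)
  for (f in indices) out <- out + image$data[, , , f]
  out <- out / length(indices)
  attr(out, "voxel_size_mm") <- image$voxel_size_mm
  out
}

voi_slab <- function(volume, voi) {
  volume[voi$x0:voi$x1, voi$y0:voi$y1, voi$z0:voi$z1, drop = FALSE]
}

#' Median of per-slice maxima
#'
#' The segmentation reference value: the averaged early-frame image is cut
#' into axial slices, the maximum voxel value within the VOI cross-section
#' is tabulated per slice, and the median over slices is returned (for an
#' even slice count, the mean of the two central values).
#'
#' @param volume 3D array (averaged early frames).
#' @param voi A [voi_box()] restricting the search.
#' @return Scalar reference value (Bq/ml).
#' @export
slice_max_reference <- function(volume, voi) {
  voi <- check_voi(voi, dim(volume))
  slab <- voi_slab(volume, voi)
  maxima <- apply(slab, 3, max)
  if (all(slab == 0)) abort("No signal inside the VOI.",
                            class = "widif_validation_error")
  median(maxima)
}

#' Threshold the carotid mask
#'
#' Voxels inside the VOI whose averaged early-frame value strictly exceeds
#' `threshold_pct`% of the [slice_max_reference()] form the binary carotid
#' mask; everything outside the VOI is zero.
#'
#' @param volume 3D array (averaged early frames) with a `voxel_size_mm`
#'   attribute, or supply `voxel_size_mm`.
#' @param voi A [voi_box()].
#' @param threshold_pct Threshold as a percentage of the reference
#'   (default 42).
#' @param voxel_size_mm Voxel size override.
#' @return A [pet_mask()].
#' @export
threshold_carotid_mask <- function(volume, voi, threshold_pct = 42,
                                   voxel_size_mm = NULL) {
  if (threshold_pct <= 0 || threshold_pct > 100) {
    abort("`threshold_pct` must lie in (0, 100].", class = "widif_validation_error")
  }
  vox <- voxel_size_mm %||% attr(volume, "voxel_size_mm")
  if (is.null(vox)) abort("Voxel size unknown; pass `voxel_size_mm`.",
                          class = "widif_validation_error")
  voi <- check_voi(voi, dim(volume))
  ref <- slice_max_reference(volume, voi)
  cut <- (threshold_pct / 100) * ref
  m <- array(FALSE, dim = dim(volume))
  m[voi$x0:voi$x1, voi$y0:voi$y1, voi$z0:voi$z1] <-
    voi_slab(volume, voi) > cut
  if (!any(m)) abort("Threshold produced an empty mask.",
                     class = "widif_validation_error")
  pet_mask(m, vox)
}

#' Extract a time-activity curve under a mask
#'
#' Per frame, the unweighted mean over mask voxels; samples are stamped at
#' frame mid-times.
#'
#' @param image A [dynamic_image()].
#' @param mask A non-empty [pet_mask()] on the same grid.
#' @return A [pet_curve()].
#' @export
extract_tac <- function(image, mask) {
  stopifnot(inherits(image, "dynamic_image"))
  m <- mask_array(mask)
  if (!identical(dim(m), dim(image$data)[1:3])) {
    abort("Mask grid does not match the image.", class = "widif_validation_error")
  }
  if (!any(m)) abort("Mask is empty.", class = "widif_validation_error")
  n_frames <- dim(image$data)[4]
  vals <- vapply(seq_len(n_frames),
                 function(f) mean(image$data[, , , f][m]), numeric(1))
  pet_curve(frame_mid_times(image$schedule), vals)
}

#' Segmentation configuration
#'
#' Bundles the manual choices of the carotid segmentation: the early-frame
#' indices, the threshold percentage and the VOI box.
#'
#' @param early_frames Non-empty integer frame indices (1-based).
#' @param threshold_pct Threshold (% of the slice-max median), default 42.
#' @param voi A [voi_box()].
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(early_frames, threshold_pct = 42, voi) {
  early_frames <- as.integer(early_frames)
  if (!length(early_frames) || anyNA(early_frames) || any(early_frames < 1)) {
    abort("`early_frames` must be positive integers.",
          class = "widif_validation_error")
  }
  if (threshold_pct <= 0 || threshold_pct > 100) {
    abort("`threshold_pct` must lie in (0, 100].", class = "widif_validation_error")
  }
  if (!inherits(voi, "voi_box")) abort("`voi` must be a voi_box.",
                                       class = "widif_schema_error")
  structure(list(early_frames = early_frames, threshold_pct = threshold_pct,
                 voi = voi),
            class = "segmentation_config")
}

#' Run the full carotid segmentation
#'
#' Averages the configured early frames, thresholds at the configured
#' percentage of the median of per-slice maxima within the VOI, and extracts
#' the carotid TAC from the full time series.
#'
#' @param image A [dynamic_image()].
#' @param config A [segmentation_config()].
#' @param min_component Optional connected-component filter: keep only
#'   6-connected components with at least this many voxels (default 0, off).
#' @return A list with `mask` ([pet_mask()]), `tac` ([pet_curve()]),
#'   `reference` (the slice-max median) and `averaged` (the early-frame
#'   average volume).
#' @export
segment_carotid <- function(image, config, min_component = 0) {
  stopifnot(inherits(image, "dynamic_image"),
            inherits(config, "segmentation_config"))
  avg <- average_frames(image, config$early_frames)
  voi <- check_voi(config$voi, dim(avg))
  ref <- slice_max_reference(avg, voi)
  mask <- threshold_carotid_mask(avg, voi, config$threshold_pct)
  if (min_component > 0) {
    mask <- filter_small_components(mask, min_component)
  }
  list(mask = mask, tac = extract_tac(image, mask), reference = ref,
       averaged = avg)
}

# Keep only 6-connected components of at least `min_voxels` voxels.
filter_small_components <- function(mask, min_voxels) {
  m <- mask_array(mask)
  labels <- array(0L, dim = dim(m))
  current <- 0L
  idx_all <- which(m)
  d <- dim(m)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      coord <- arrayInd(v, d)
      for (a in 1:3) for (s in c(-1L, 1L)) {
        nb <- coord; nb[a] <- nb[a] + s
        if (nb[a] < 1 || nb[a] > d[a]) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (m[lin] && labels[lin] == 0L) {
          labels[lin] <- current
          queue <- c(queue, lin)
        }
      }
    }
  }
  keep <- which(tabulate(labels[m]) >= min_voxels)
  pet_mask(array(labels %in% keep & m, dim = d), mask$voxel_size_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
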