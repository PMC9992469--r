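#' Dynamic PET image container
#'
#' A 4D array of activity concentration (Bq/ml) on axes (x, y, axial, frame),
#' together with the voxel size in mm and the frame schedule. The package's
#' canonical orientation puts the axial direction on the third axis with the
#' inferior (neck) end at index 1.
#'
#' @param data 4D numeric array (x, y, z-axial, frame), finite values.
#' @param voxel_size_mm Length-3 positive numeric, voxel edge lengths in mm.
#' @param schedule A [frame_schedule()] whose length equals `dim(data)[4]`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, voxel_size_mm, schedule) {
  if (length(dim(data)) != 4) {
    abort("`data` must be a 4D array (x, y, axial, frame).",
          class = "widif_shape_error")
  }
  schedule <- as_frame_schedule(schedule)
  if (dim(data)[4] != nrow(schedule)) {
    abort(sprintf("Image has %d frames but schedule has %d.",
                  dim(data)[4], nrow(schedule)),
          class = "widif_schema_error")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3 || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    abort("`voxel_size_mm` must be three positive numbers.",
          class = "widif_validation_error")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    abort("Image values must be finite.", class = "widif_validation_error")
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %.2f x %.2f x %.2f mm, span %.0f s\n",
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              max(x$schedule$start_s + x$schedule$duration_s)))
  invisible(x)
}

#' Binary mask on an image grid
#'
#' @param data 3D array of 0/1 (logical or numeric).
#' @param voxel_size_mm Length-3 positive numeric (mm).
#' @return An object of class `pet_mask`; `data` is stored as logical.
#' @export
pet_mask <- function(data, voxel_size_mm) {
  if (length(dim(data)) != 3) {
    abort("`data` must be a 3D array.", class = "widif_shape_error")
  }
  if (anyNA(data)) abort("Mask values must not be NA.", class = "widif_validation_error")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) {
      abort("Mask values must be 0/1.", class = "widif_validation_error")
    }
    data <- array(data != 0, dim = dim(data))
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0)) {
    abort("`voxel_size_mm` must be three positive numbers.",
          class = "widif_validation_error")
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm),
            class = "pet_mask")
}

#' @export
print.pet_mask <- function(x, ...) {
  cat(sprintf("<pet_mask> %s voxels, %d set\n",
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

mask_array <- function(mask) {
  if (inherits(mask, "pet_mask")) return(mask$data)
  if (is.array(mask) && length(dim(mask)) == 3) return(mask != 0)
  abort("Expected a pet_mask or 3D array.", class = "widif_schema_error")
}

#' Volume-of-interest box
#'
#' Inclusive 1-based index ranges per axis, used to restrict segmentation to
#' a hand-drawn region around the carotid arteries.
#'
#' @param x0,x1,y0,y1,z0,z1 Integer index bounds, `x0 <= x1` etc.
#' @return An object of class `voi_box`.
#' @export
voi_box <- function(x0, x1, y0, y1, z0, z1) {
  v <- as.integer(c(x0, x1, y0, y1, z0, z1))
  if (anyNA(v)) abort("VOI bounds must be integers.", class = "widif_validation_error")
  if (v[1] > v[2] || v[3] > v[4] || v[5] > v[6] || any(v < 1)) {
    abort("VOI box is empty or out of bounds.", class = "widif_validation_error")
  }
  structure(list(x0 = v[1], x1 = v[2], y0 = v[3], y1 = v[4],
                 z0 = v[5], z1 = v[6]),
            class = "voi_box")
}

check_voi <- function(voi, dim3) {
  if (!inherits(voi, "voi_box")) abort("Expected a voi_box.", class = "widif_schema_error")
  if (voi$x1 > dim3[1] || voi$y1 > dim3[2] || voi$z1 > dim3[3]) {
    abort("VOI box exceeds image bounds.", class = "widif_validation_error")
  }
  voi
}

#' Bounding VOI of a mask, with margin
#'
#' Convenience for building a carotid VOI from a known (e.g. phantom truth)
#' mask: the tight bounding box of the set voxels expanded by `margin` voxels
#' per axis, clipped to the grid.
#'
#' @param mask A [pet_mask()].
#' @param margin Non-negative integer margin in voxels (recycled to length 3).
#' @return A [voi_box()].
#' @export
voi_from_mask <- function(mask, margin = 3) {
  m <- mask_array(mask)
  if (!any(m)) abort("Mask is empty.", class = "widif_validation_error")
  margin <- rep_len(as.integer(margin), 3)
  idx <- which(m, arr.ind = TRUE)
  d <- dim(m)
  voi_box(max(1L, min(idx[, 1]) - margin[1]), min(d[1], max(idx[, 1]) + margin[1]),
          max(1L, min(idx[, 2]) - margin[2]), min(d[2], max(idx[, 2]) + margin[2]),
          max(1L, min(idx[, 3]) - margin[3]), min(d[3], max(idx[, 3]) + margin[3]))
}

#' Read a dynamic PET scan
#'
#' Reads a 4D NIfTI-1 image plus its JSON frame-schedule sidecar, reorients
#' to the canonical axes order (axial on the third axis, inferior at low
#' indices, i.e. RAS) when the file carries an orientation, and returns a
#' [dynamic_image()]. Values are taken as Bq/ml.
#'
#' @param image_path Path to a 4D `.nii`/`.nii.gz` file.
#' @param schedule_path Path to the JSON sidecar (see
#'   [read_frame_schedule()]).
#' @return A [dynamic_image()].
#' @export
read_dynamic <- function(image_path, schedule_path) {
  img <- RNifti::readNifti(image_path)
  img <- reorient_canonical(img)
  d <- dim(img)
  if (length(d) != 4) {
    abort(sprintf("Expected a 4D image, got %d dimensions.", length(d)),
          class = "widif_shape_error")
  }
  schedule <- read_frame_schedule(schedule_path)
  if (d[4] != nrow(schedule)) {
    abort(sprintf("Image has %d frames but schedule has %d.", d[4], nrow(schedule)),
          class = "widif_schema_error")
  }
  vox <- RNifti::pixdim(img)[1:3]
  dynamic_image(array(as.numeric(img), dim = d), vox, schedule)
}

# Reorient to RAS if the header carries a usable xform; identity otherwise.
reorient_canonical <- function(img) {
  ori <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (!is.null(ori) && nzchar(ori) && ori != "RAS") {
    img <- tryCatch({ RNifti::orientation(img) <- "RAS"; img },
                    warning = function(w) img, error = function(e) img)
  }
  img
}

#' Write a volume or mask as NIfTI-1
#'
#' Writes a 3D/4D array, [pet_mask()] or [dynamic_image()] to a NIfTI-1 file
#' with its voxel geometry; masks are written as unsigned bytes.
#'
#' @param volume Array, `pet_mask` or `dynamic_image`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size, required when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size_mm = NULL) {
  if (inherits(volume, "dynamic_image")) {
    arr <- volume$data; vox <- volume$voxel_size_mm; datatype <- "double"
  } else if (inherits(volume, "pet_mask")) {
    arr <- array(as.integer(volume$data), dim = dim(volume$data))
    vox <- volume$voxel_size_mm; datatype <- "uint8"
  } else if (is.array(volume) && length(dim(volume)) %in% c(3, 4)) {
    if (is.null(voxel_size_mm)) {
      abort("`voxel_size_mm` is required for a bare array.",
            class = "widif_validation_error")
    }
    arr <- volume; vox <- as.numeric(voxel_size_mm); datatype <- "double"
  } else {
    abort("`volume` must be a 3D/4D array, pet_mask or dynamic_image.",
          class = "widif_shape_error")
  }
  if (anyNA(arr) || any(!is.finite(arr))) {
    abort("Volume values must be finite.", class = "widif_validation_error")
  }
  attr(arr, "pixdim") <- c(vox, rep(1, length(dim(arr)) - 3))
  im <- RNifti::asNifti(arr, datatype = datatype)
  ok <- tryCatch({ RNifti::writeNifti(im, path); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    abort(paste0("Could not write ", path), class = "widif_io_error")
  }
  invisible(path)
}

#' Read a 3D volume or binary mask
#'
#' @param path NIfTI file path.
#' @param voxel_size_mm Override for the voxel size; taken from the header by
#'   default.
#' @return `read_mask()` returns a [pet_mask()]; `read_volume()` a plain 3D
#'   array with a `voxel_size_mm` attribute.
#' @export
read_mask <- function(path, voxel_size_mm = NULL) {
  img <- reorient_canonical(RNifti::readNifti(path))
  if (length(dim(img)) != 3) abort("Expected a 3D mask.", class = "widif_shape_error")
  vox <- if (is.null(voxel_size_mm)) RNifti::pixdim(img)[1:3] else voxel_size_mm
  pet_mask(array(as.numeric(img) != 0, dim = dim(img)), vox)
}

#' @rdname read_mask
#' @export
read_volume <- function(path) {
  img <- reorient_canonical(RNifti::readNifti(path))
  if (length(dim(img)) != 3) abort("Expected a 3D volume.", class = "widif_shape_error")
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[1:3]
  out
}
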