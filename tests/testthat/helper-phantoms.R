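# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default dynamic phantom (study conditions: 5.5 mm tubes, 2.3 mm PSF, noise).
default_phantom <- function() {
  cached("default_phantom", function() generate_dynamic_phantom(dynamic_phantom_spec()))
}

# Noise-free variant of the default phantom.
noise_free_phantom <- function() {
  cached("noise_free_phantom",
         function() generate_dynamic_phantom(dynamic_phantom_spec(noise_scale = 0)))
}

# Small noise-free phantom with PSF matched to the 2.1-mm PVC kernel, for
# grid-search and voxelwise tests.
small_phantom <- function() {
  cached("small_phantom", function() {
    generate_dynamic_phantom(
      dynamic_phantom_spec(grid_dim = c(64, 64, 36), noise_scale = 0,
                           psf_fwhm_mm = 2.1))
  })
}

# Static tube phantom at the default (matched 2.1 mm) settings.
static_phantom <- function() {
  cached("static_phantom", function() generate_static_tube_phantom(static_phantom_spec()))
}

scanner_voxels <- c(0.98, 0.98, 2.79)

# Independent brute-force oracle for smoothing at mask voxels: explicit dense
# convolution with the truncated, normalised 3D Gaussian kernel and
# edge-clamped (replicate) indexing. O(N_mask * kernel); used on tiny masks.
dense_smooth_at <- function(vol, fwhm_mm, voxel_size_mm, at_idx) {
  sigma <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size_mm
  kern1 <- lapply(sigma, function(s) {
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k / sum(k)
  })
  k3 <- outer(outer(kern1[[1]], kern1[[2]]), kern1[[3]])
  rs <- (dim(k3) - 1) / 2
  d <- dim(vol)
  out <- numeric(nrow(at_idx))
  for (v in seq_len(nrow(at_idx))) {
    acc <- 0
    for (i in seq_len(dim(k3)[1])) for (j in seq_len(dim(k3)[2]))
      for (l in seq_len(dim(k3)[3])) {
        x <- min(max(at_idx[v, 1] + i - rs[1] - 1, 1), d[1])
        y <- min(max(at_idx[v, 2] + j - rs[2] - 1, 1), d[2])
        z <- min(max(at_idx[v, 3] + l - rs[3] - 1, 1), d[3])
        acc <- acc + k3[i, j, l] * vol[x, y, z]
      }
    out[v] <- acc
  }
  out
}

# Random compact interior box mask on a small grid.
random_interior_mask <- function(dim3 = c(24, 24, 16), voxel_size_mm = scanner_voxels) {
  lo <- c(sample(8:12, 1), sample(8:12, 1), sample(6:8, 1))
  sz <- c(sample(2:5, 1), sample(2:5, 1), sample(2:4, 1))
  m <- array(FALSE, dim = dim3)
  m[lo[1]:(lo[1] + sz[1]), lo[2]:(lo[2] + sz[2]), lo[3]:(lo[3] + sz[3])] <- TRUE
  pet_mask(m, voxel_size_mm)
}
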