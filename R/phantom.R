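#' Arterial input-function model
#'
#' Parametric bolus shape used by the phantoms: a gamma-variate first pass
#' plus an exponentially decaying recirculation tail,
#' \deqn{C_a(t) = A ((t-t_0)/s)^k e^{k (1 - (t-t_0)/s)}
#'   + f A (1 - e^{-(t-t_0)/s}) e^{-\lambda (t-t_0)}, \quad t > t_0,}
#' and zero before the appearance time \eqn{t_0}. The gamma-variate is
#' peak-normalised by construction: with `tail_fraction = 0` the curve equals
#' exactly `amplitude` at its peak, `t0 + scale` (the scale parameter is the
#' time-to-peak after appearance).
#'
#' Defaults mimic a controlled 10-ml bolus at 1 ml/s with saline flush:
#' appearance at 10 s, peak at 25 s, and a tail carrying roughly a sixth of
#' the peak concentration, decaying slowly over the 10-min scan.
#'
#' @param amplitude Peak concentration A (Bq/ml).
#' @param t0_s Appearance time (s).
#' @param shape Gamma shape k (unitless, > 0).
#' @param scale_s Gamma scale s (s, > 0).
#' @param tail_fraction Tail amplitude as a fraction of A, in [0, 1).
#' @param tail_decay_per_s Tail decay rate (1/s, >= 0).
#' @return An object of class `input_function_model`.
#' @export
input_function_model <- function(amplitude = 1e5, t0_s = 10, shape = 3,
                                 scale_s = 15, tail_fraction = 0.15,
                                 tail_decay_per_s = 0.002) {
  if (amplitude < 0) abort("`amplitude` must be >= 0.", class = "widif_validation_error")
  if (scale_s <= 0 || shape <= 0) {
    abort("`shape` and `scale_s` must be positive.", class = "widif_validation_error")
  }
  if (tail_fraction < 0 || tail_fraction >= 1) {
    abort("`tail_fraction` must lie in [0, 1).", class = "widif_validation_error")
  }
  structure(list(amplitude = amplitude, t0_s = t0_s, shape = shape,
                 scale_s = scale_s, tail_fraction = tail_fraction,
                 tail_decay_per_s = tail_decay_per_s),
            class = "input_function_model")
}

#' Evaluate the arterial input model
#'
#' @param model An [input_function_model()].
#' @param times Non-negative sample times (s).
#' @return A [pet_curve()].
#' @export
model_input_function <- function(model, times) {
  if (!inherits(model, "input_function_model")) {
    abort("`model` must be an input_function_model.", class = "widif_schema_error")
  }
  times <- as.numeric(times)
  if (any(times < 0)) abort("`times` must be >= 0.", class = "widif_validation_error")
  pet_curve(times, input_function_values(model, times))
}

input_function_values <- function(model, times) {
  u <- (times - model$t0_s) / model$scale_s
  v <- numeric(length(times))
  pos <- u > 0
  up <- u[pos]
  bolus <- model$amplitude * up^model$shape * exp(model$shape * (1 - up))
  tail <- model$tail_fraction * model$amplitude * (1 - exp(-up)) *
    exp(-model$tail_decay_per_s * (times[pos] - model$t0_s))
  v[pos] <- bolus + tail
  v
}

#' Single-tissue compartment tissue response
#'
#' Solves the one-tissue compartment model
#' \deqn{dC_T/dt = F C_a(t) - (F/V_d) C_T(t)} for a given arterial input,
#' i.e. \eqn{C_T(t) = F \int_0^t C_a(s) e^{-k_2 (t-s)} ds} with
#' \eqn{k_2 = F/V_d}. The convolution is evaluated exactly for the
#' piecewise-linear interpolant of the input on a fine grid (step <= 0.5 s),
#' then sampled at `times`.
#'
#' @param input Arterial curve (data frame with `time_s`, `activity_Bq_ml`).
#' @param flow Perfusion F in ml/cm^3/min (> 0).
#' @param vd Distribution volume V_d in ml/cm^3 (> 0).
#' @param times Output sample times (s), within the input support.
#' @return A [pet_curve()] of tissue concentration (Bq/ml).
#' @export
tissue_response <- function(input, flow, vd, times) {
  if (flow <= 0 || vd <= 0) {
    abort("`flow` and `vd` must be positive.", class = "widif_validation_error")
  }
  input <- as_pet_curve(input)
  times <- as.numeric(times)
  k2_s <- (flow / vd) / 60
  f_s <- flow / 60
  grid <- fine_grid(c(input$time_s, times), step = 0.5)
  ca <- curve_interp(input, grid, rule = 2)
  conv <- exp_convolve(grid, ca, k2_s)
  pet_curve(times, f_s * approx(grid, conv, xout = times, rule = 2)$y)
}

# Uniform fine grid covering all the supplied times.
fine_grid <- function(times, step = 0.5) {
  t0 <- min(0, min(times))
  t1 <- max(times)
  seq(t0, t1 + step / 2, by = step)
}

# Exact convolution of the piecewise-linear curve (t, c) with exp(-k t):
# I(t_i) = int_0^{t_i} c(s) exp(-k (t_i - s)) ds, computed recursively.
exp_convolve <- function(t, c, k) {
  n <- length(t)
  out <- numeric(n)
  if (n < 2) return(out)
  h <- diff(t)
  for (i in 2:n) {
    hi <- h[i - 1]
    c0 <- c[i - 1]
    m <- (c[i] - c0) / hi
    if (k * hi < 1e-12) {
      out[i] <- out[i - 1] + (c0 + c[i]) / 2 * hi
    } else {
      E <- exp(-k * hi)
      out[i] <- out[i - 1] * E + c0 * (1 - E) / k + m * (hi / k - (1 - E) / k^2)
    }
  }
  out
}

#' Dynamic brain-phantom specification
#'
#' Describes a synthetic head: two carotid-like tubes in the neck (lower)
#' third of the grid carrying the arterial input curve, and an ellipsoidal
#' brain in the upper part whose grey-matter shell and white-matter core obey
#' single-tissue compartment kinetics. The phantom is blurred with a Gaussian
#' point-spread function, averaged over the frame schedule, and optionally
#' degraded with frame-duration-dependent Gaussian noise with
#' `SD = noise_scale * sqrt(max(value, 0) / duration_s)`.
#'
#' Defaults: 96 x 96 x 48 grid of 0.98 x 0.98 x 2.79 mm voxels, 5.5-mm
#' tubes, PSF 2.3 mm FWHM, GM F = 0.64 and WM F = 0.20 ml/cm^3/min with
#' V_d = 0.9 and 0.8 ml/cm^3, and the standard 26-frame schedule.
#'
#' @param grid_dim Length-3 integer grid size.
#' @param voxel_size_mm Voxel size (mm).
#' @param tube_diameter_mm Carotid tube diameter (mm, > 0).
#' @param tube_z_extent Axial index range (length 2) spanned by the tubes.
#' @param gm_flow,wm_flow Perfusion (ml/cm^3/min).
#' @param gm_vd,wm_vd Distribution volumes (ml/cm^3).
#' @param psf_fwhm_mm Point-spread FWHM (mm, >= 0).
#' @param noise_scale Noise magnitude (0 disables noise).
#' @param schedule A [frame_schedule()].
#' @param input_model An [input_function_model()].
#' @param seed Integer RNG seed for the noise.
#' @return An object of class `dynamic_phantom_spec`.
#' @export
dynamic_phantom_spec <- function(grid_dim = c(96, 96, 48),
                                 voxel_size_mm = c(0.98, 0.98, 2.79),
                                 tube_diameter_mm = 5.5,
                                 tube_z_extent = NULL,
                                 gm_flow = 0.64, gm_vd = 0.9,
                                 wm_flow = 0.20, wm_vd = 0.8,
                                 psf_fwhm_mm = 2.3,
                                 noise_scale = 20,
                                 schedule = default_frame_schedule(),
                                 input_model = input_function_model(),
                                 seed = 1L) {
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 3 || any(grid_dim < 8)) {
    abort("`grid_dim` must be three integers >= 8.", class = "widif_validation_error")
  }
  if (tube_diameter_mm <= 0) abort("Tube diameter must be positive.",
                                   class = "widif_validation_error")
  if (any(c(gm_flow, gm_vd, wm_flow, wm_vd) <= 0)) {
    abort("F and V_d must be positive.", class = "widif_validation_error")
  }
  if (psf_fwhm_mm < 0) abort("`psf_fwhm_mm` must be >= 0.",
                             class = "widif_validation_error")
  if (is.null(tube_z_extent)) {
    tube_z_extent <- c(1L, max(2L, floor(grid_dim[3] / 3)))
  }
  structure(list(grid_dim = grid_dim, voxel_size_mm = as.numeric(voxel_size_mm),
                 tube_diameter_mm = tube_diameter_mm,
                 tube_z_extent = as.integer(tube_z_extent),
                 gm_flow = gm_flow, gm_vd = gm_vd,
                 wm_flow = wm_flow, wm_vd = wm_vd,
                 psf_fwhm_mm = psf_fwhm_mm, noise_scale = noise_scale,
                 schedule = as_frame_schedule(schedule),
                 input_model = input_model, seed = as.integer(seed)),
            class = "dynamic_phantom_spec")
}

# Fractional in-plane occupancy of a circle of given centre/radius (mm) on
# the voxel grid, by `factor`-fold in-plane supersampling.
disc_occupancy <- function(grid_dim, voxel_size_mm, centre_mm, radius_mm,
                           factor = 4) {
  nx <- grid_dim[1]; ny <- grid_dim[2]
  sx <- voxel_size_mm[1]; sy <- voxel_size_mm[2]
  sub <- (seq_len(factor) - 0.5) / factor
  xs <- rep((seq_len(nx) - 1), each = factor) * sx + rep(sub, nx) * sx
  ys <- rep((seq_len(ny) - 1), each = factor) * sy + rep(sub, ny) * sy
  inside <- outer((xs - centre_mm[1])^2, (ys - centre_mm[2])^2, `+`) <= radius_mm^2
  # reduce factor x factor sub-voxel blocks to fractional voxel occupancy
  arr <- array(inside, dim = c(factor, nx, factor, ny))
  apply(arr, c(2, 4), mean)
}

#' Generate the dynamic brain phantom
#'
#' Builds the noise-free truth (tubes carry the arterial curve, brain voxels
#' the tissue response of their region, everything else zero), averages over
#' the frame intervals, blurs each frame with the PSF, and adds seeded
#' frame-duration-dependent noise. Frame averaging and blurring are both
#' linear, so their order does not affect the result.
#'
#' @param spec A [dynamic_phantom_spec()].
#' @return A list with elements `image` (a [dynamic_image()]) and `truth`
#'   (list: `input` true fine-grid curve, `input_frames` frame-averaged true
#'   input, `carotid_mask`, `gm_mask`, `wm_mask`, `flow_map`, `vd_map`,
#'   `noise_free` noise-free blurred [dynamic_image()]).
#' @export
generate_dynamic_phantom <- function(spec) {
  if (!inherits(spec, "dynamic_phantom_spec")) {
    abort("`spec` must be a dynamic_phantom_spec.", class = "widif_schema_error")
  }
  gd <- spec$grid_dim; vox <- spec$voxel_size_mm
  if (spec$tube_diameter_mm < 2 * min(vox[1:2])) {
    warn("Tube diameter is below two in-plane voxels (sub-resolution object).")
  }
  sched <- spec$schedule
  n_frames <- nrow(sched)
  span <- max(sched$start_s + sched$duration_s)
  grid <- seq(0, span, by = 0.5)
  input_fine <- model_input_function(spec$input_model, grid)

  # frame-averaged curves (truth before blurring)
  input_frames <- resample_to_frames(input_fine, sched)
  gm_frames <- resample_to_frames(
    tissue_response(input_fine, spec$gm_flow, spec$gm_vd, grid), sched)
  wm_frames <- resample_to_frames(
    tissue_response(input_fine, spec$wm_flow, spec$wm_vd, grid), sched)

  # geometry: two tubes in the neck, ellipsoidal brain above
  centre_mm <- (gd[1:2] / 2) * vox[1:2]
  sep_mm <- 8 * vox[1] # tube centres +/- 8 in-plane voxels from midline
  r_mm <- spec$tube_diameter_mm / 2
  occ_l <- disc_occupancy(gd, vox, centre_mm + c(-sep_mm, 0), r_mm)
  occ_r <- disc_occupancy(gd, vox, centre_mm + c(sep_mm, 0), r_mm)
  tube_occ2d <- occ_l + occ_r
  tube_z <- seq(max(1L, spec$tube_z_extent[1]), min(gd[3], spec$tube_z_extent[2]))

  # Ellipsoidal brain confined to the upper axial part, strictly above the
  # carotid sleeve's reach (the phantom's surroundings are empty, so the
  # sleeve must not sample brain): with the default 10-step sleeve dilation,
  # the brain floor sits > 10 voxels above the tube tops.
  z_floor <- min(gd[3], max(spec$tube_z_extent[2] + 11L,
                            floor(0.55 * gd[3]) + 1L))
  xs <- (seq_len(gd[1]) - 0.5) * vox[1] - centre_mm[1]
  ys <- (seq_len(gd[2]) - 0.5) * vox[2] - centre_mm[2]
  a_mm <- 0.40 * gd[1] * vox[1]
  c_mm <- (gd[3] - z_floor + 1) * vox[3] / 2
  zc_mm <- ((z_floor - 1) + gd[3]) / 2 * vox[3]
  zs <- (seq_len(gd[3]) - 0.5) * vox[3] - zc_mm
  rx2 <- outer((xs / a_mm)^2, (ys / a_mm)^2, `+`)
  dist2 <- outer(rx2, (zs / c_mm)^2, `+`)
  brain <- dist2 <= 1
  wm <- dist2 <= 0.6^2
  gm <- brain & !wm

  tube_occ <- array(0, dim = gd)
  for (z in tube_z) tube_occ[, , z] <- tube_occ2d
  # carotids trump brain where they would overlap (they should not)
  gm[tube_occ > 0] <- FALSE
  wm[tube_occ > 0] <- FALSE

  flow_map <- array(0, dim = gd)
  vd_map <- array(0, dim = gd)
  flow_map[gm] <- spec$gm_flow; vd_map[gm] <- spec$gm_vd
  flow_map[wm] <- spec$wm_flow; vd_map[wm] <- spec$wm_vd

  truth_frames <- array(0, dim = c(gd, n_frames))
  for (f in seq_len(n_frames)) {
    vol <- tube_occ * input_frames$activity_Bq_ml[f]
    vol[gm] <- gm_frames$activity_Bq_ml[f]
    vol[wm] <- wm_frames$activity_Bq_ml[f]
    truth_frames[, , , f] <- vol
  }
  blurred <- gaussian_smooth(truth_frames, spec$psf_fwhm_mm, vox)

  noisy <- blurred
  if (spec$noise_scale > 0) {
    set.seed(spec$seed)
    for (f in seq_len(n_frames)) {
      sdv <- spec$noise_scale *
        sqrt(pmax(blurred[, , , f], 0) / sched$duration_s[f])
      noisy[, , , f] <- blurred[, , , f] +
        array(rnorm(prod(gd), sd = 1), dim = gd) * sdv
    }
  }

  list(
    image = dynamic_image(noisy, vox, sched),
    truth = list(
      input = input_fine,
      input_frames = input_frames,
      carotid_mask = pet_mask(tube_occ >= 0.5, vox),
      carotid_occupancy = tube_occ,
      gm_mask = pet_mask(gm, vox),
      wm_mask = pet_mask(wm, vox),
      flow_map = flow_map,
      vd_map = vd_map,
      noise_free = dynamic_image(blurred, vox, sched)
    )
  )
}

#' Static tube-phantom specification
#'
#' A hot tube of known concentration submerged in a non-radioactive water
#' cylinder — the classic validation object for mask-plus-PVC recovery.
#' Defaults follow the 6-mm-diameter tube at 2.1 MBq/ml in a 20-cm cylinder,
#' simulated on the scanner voxel grid over about 5 cm of axial extent.
#'
#' @param tube_diameter_mm Tube diameter (mm).
#' @param tube_concentration Tube activity concentration (Bq/ml).
#' @param cylinder_diameter_mm Water cylinder diameter (mm).
#' @param background_concentration Cylinder activity (Bq/ml, default 0).
#' @param grid_dim Length-3 grid size; default covers the cylinder.
#' @param voxel_size_mm Voxel size (mm).
#' @param psf_fwhm_mm Simulation PSF FWHM (mm).
#' @param noise_scale Additive Gaussian noise SD as a fraction of the tube
#'   concentration (0 disables).
#' @param supersample In-plane supersampling factor for the analytic tube
#'   boundary (>= 4 recommended).
#' @param seed RNG seed.
#' @return An object of class `static_phantom_spec`.
#' @export
static_phantom_spec <- function(tube_diameter_mm = 6,
                                tube_concentration = 2.1e6,
                                cylinder_diameter_mm = 200,
                                background_concentration = 0,
                                grid_dim = NULL,
                                voxel_size_mm = c(0.98, 0.98, 2.79),
                                psf_fwhm_mm = 2.1,
                                noise_scale = 0,
                                supersample = 4,
                                seed = 1L) {
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (is.null(grid_dim)) {
    nxy <- ceiling(cylinder_diameter_mm / voxel_size_mm[1]) + 8
    grid_dim <- c(nxy, nxy, ceiling(50 / voxel_size_mm[3]))
  }
  if (tube_diameter_mm <= 0 || tube_concentration < 0 || psf_fwhm_mm < 0) {
    abort("Invalid static phantom parameters.", class = "widif_validation_error")
  }
  if (supersample < 1) abort("`supersample` must be >= 1.",
                             class = "widif_validation_error")
  structure(list(tube_diameter_mm = tube_diameter_mm,
                 tube_concentration = tube_concentration,
                 cylinder_diameter_mm = cylinder_diameter_mm,
                 background_concentration = background_concentration,
                 grid_dim = as.integer(grid_dim),
                 voxel_size_mm = voxel_size_mm,
                 psf_fwhm_mm = psf_fwhm_mm, noise_scale = noise_scale,
                 supersample = as.integer(supersample), seed = as.integer(seed)),
            class = "static_phantom_spec")
}

#' Generate the static tube phantom
#'
#' The analytic tube indicator is supersampled in-plane (the tube is parallel
#' to the axial axis, so the boundary is purely in-plane), reduced to
#' fractional voxel occupancy, scaled to the tube concentration on top of the
#' cylinder background, blurred with the PSF and optionally degraded with
#' noise.
#'
#' @param spec A [static_phantom_spec()].
#' @return A list with `image` (3D array with `voxel_size_mm` attribute) and
#'   `truth` (list: `tube_mask` occupancy-majority [pet_mask()],
#'   `tube_occupancy` fractional array, `cylinder_mask`, `concentration`,
#'   `noise_free` blurred noise-free array).
#' @export
generate_static_tube_phantom <- function(spec) {
  if (!inherits(spec, "static_phantom_spec")) {
    abort("`spec` must be a static_phantom_spec.", class = "widif_schema_error")
  }
  gd <- spec$grid_dim; vox <- spec$voxel_size_mm
  centre_mm <- (gd[1:2] / 2) * vox[1:2]
  occ2d <- disc_occupancy(gd, vox, centre_mm, spec$tube_diameter_mm / 2,
                          factor = spec$supersample)
  cyl2d <- disc_occupancy(gd, vox, centre_mm, spec$cylinder_diameter_mm / 2,
                          factor = 2)
  occ <- array(rep(occ2d, gd[3]), dim = gd)
  cyl <- array(rep(cyl2d, gd[3]), dim = gd)
  truth_vol <- spec$background_concentration * pmax(cyl - occ, 0) +
    spec$tube_concentration * occ
  blurred <- gaussian_smooth(truth_vol, spec$psf_fwhm_mm, vox)
  img <- blurred
  if (spec$noise_scale > 0) {
    set.seed(spec$seed)
    img <- img + array(rnorm(prod(gd),
                             sd = spec$noise_scale * spec$tube_concentration),
                       dim = gd)
  }
  attr(img, "voxel_size_mm") <- vox
  list(
    image = img,
    truth = list(
      tube_mask = pet_mask(occ >= 0.5, vox),
      tube_occupancy = occ,
      cylinder_mask = pet_mask(cyl >= 0.5, vox),
      concentration = spec$tube_concentration,
      noise_free = blurred
    )
  )
}
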