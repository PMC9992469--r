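#' Pipeline run configuration
#'
#' Gathers every knob of an end-to-end run. Defaults mirror the method's
#' chosen operating point: a 42% threshold, a 2.1-mm PVC kernel, the
#' 8-to-10-step dilation sleeve, a 13-s dispersion constant and a 300-s fit
#' window.
#'
#' @param image,schedule Paths to the 4D NIfTI scan and its JSON sidecar.
#' @param frames Early-frame indices for segmentation (1-based).
#' @param voi VOI bounds: a [voi_box()] or six integers
#'   (x0, x1, y0, y1, z0, z1).
#' @param threshold_pct Mask threshold (% of the slice-max median).
#' @param kernel_fwhm_mm PVC Gaussian kernel FWHM (mm).
#' @param sleeve_inner,sleeve_outer Sleeve dilation steps.
#' @param tau_s Dispersion time constant (s) for blood-curve conditioning.
#' @param fit_window_s Kinetic fit window (s).
#' @param k2_min,k2_max,k2_n Clearance grid bounds (1/min) and size.
#' @param brain_mask,gm_mask Optional mask paths: `brain_mask` triggers
#'   voxelwise parametric maps, `gm_mask` a regional GM fit.
#' @param blood_curve,blood_samples Optional paths to a raw sampler curve
#'   and calibration samples (TSV); enables BSIF preparation and
#'   IDIF-vs-BSIF comparison.
#' @param out_dir Output directory (created if missing).
#' @param seed Seed recorded in the report (analysis stages are
#'   deterministic; the seed governs phantom generation upstream).
#' @return A list of class `run_config`.
#' @export
run_config <- function(image, schedule, frames, voi,
                       threshold_pct = 42, kernel_fwhm_mm = 2.1,
                       sleeve_inner = 8, sleeve_outer = 10,
                       tau_s = 13, fit_window_s = 300,
                       k2_min = 0.01, k2_max = 3, k2_n = 100,
                       brain_mask = NULL, gm_mask = NULL,
                       blood_curve = NULL, blood_samples = NULL,
                       out_dir = ".", seed = 1L) {
  if (!inherits(voi, "voi_box")) {
    if (length(voi) != 6) abort("`voi` must be a voi_box or six integers.",
                                class = "widif_validation_error")
    voi <- voi_box(voi[1], voi[2], voi[3], voi[4], voi[5], voi[6])
  }
  cfg <- list(image = image, schedule = schedule,
              frames = as.integer(frames), voi = voi,
              threshold_pct = threshold_pct, kernel_fwhm_mm = kernel_fwhm_mm,
              sleeve_inner = sleeve_inner, sleeve_outer = sleeve_outer,
              tau_s = tau_s, fit_window_s = fit_window_s,
              k2_min = k2_min, k2_max = k2_max, k2_n = k2_n,
              brain_mask = brain_mask, gm_mask = gm_mask,
              blood_curve = blood_curve, blood_samples = blood_samples,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; relative paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path),
                                class = "widif_io_error")
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  extra <- setdiff(names(y), allowed)
  if (length(extra)) {
    abort(paste0("Unknown config keys: ", paste(extra, collapse = ", ")),
          class = "widif_schema_error")
  }
  base_dir <- dirname(normalizePath(path))
  for (key in c("image", "schedule", "brain_mask", "gm_mask",
                "blood_curve", "blood_samples")) {
    if (!is.null(y[[key]]) && !grepl("^/", y[[key]])) {
      y[[key]] <- file.path(base_dir, y[[key]])
    }
  }
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "widif_pipeline_error")
  })
}

#' Run the full IDIF pipeline
#'
#' Executes segmentation, partial-volume correction, IDIF extraction,
#' optional blood-curve conditioning, kinetic modelling and agreement
#' metrics on a scan, writing all intermediate products and a
#' machine-readable JSON report to the configured output directory. Every
#' resolved parameter is echoed in the report, so a run is reproducible from
#' the report alone.
#'
#' @param config A [run_config()].
#' @return The report, invisibly, as a named list (also written to
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("`config` must be a run_config.", class = "widif_schema_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  image <- stage("load", read_dynamic(config$image, config$schedule))

  seg <- stage("segmentation", {
    if (!length(config$frames)) abort("No early frames configured.")
    segment_carotid(image,
                    segmentation_config(config$frames, config$threshold_pct,
                                        config$voi))
  })

  pvc <- stage("pvc", {
    factors <- compute_pvc_factors(seg$mask, config$kernel_fwhm_mm)
    sleeve <- sleeve_tissue_mask(seg$mask, config$sleeve_inner,
                                 config$sleeve_outer)
    tissue_tac <- extract_tac(image, sleeve)
    idif <- correct_blood_curve(seg$tac, tissue_tac, factors)
    list(factors = factors, sleeve = sleeve, tissue_tac = tissue_tac,
         idif = idif)
  })

  bsif <- NULL
  if (!is.null(config$blood_curve)) {
    bsif <- stage("bsif", {
      raw <- read_curve(config$blood_curve)
      samples <- if (!is.null(config$blood_samples)) {
        read_curve(config$blood_samples)
      }
      prepare_bsif(raw, samples, image$schedule,
                   reference_tac = pvc$idif, tau_s = config$tau_s)
    })
  }

  k2_grid <- default_k2_grid(config$k2_n, config$k2_min, config$k2_max)
  span <- max(image$schedule$start_s + image$schedule$duration_s)
  idif_dense <- pet_curve(
    c(0, pvc$idif$time_s, span),
    c(0, pvc$idif$activity_Bq_ml,
      pvc$idif$activity_Bq_ml[nrow(pvc$idif)]))

  kinetics <- stage("kinetics", {
    res <- list()
    if (!is.null(config$gm_mask)) {
      gm <- read_mask(config$gm_mask)
      gm_tac <- extract_tac(image, gm)
      basis <- make_basis(idif_dense, image$schedule, k2_grid)
      res$gm_fit <- fit_1tcm(gm_tac, basis, fit_window_s = config$fit_window_s)
      if (!is.null(bsif)) {
        bsif_dense <- pet_curve(
          c(0, bsif$bsif$time_s, span),
          c(0, bsif$bsif$activity_Bq_ml,
            bsif$bsif$activity_Bq_ml[nrow(bsif$bsif)]))
        basis_b <- make_basis(bsif_dense, image$schedule, k2_grid)
        res$gm_fit_bsif <- fit_1tcm(gm_tac, basis_b,
                                    fit_window_s = config$fit_window_s)
      }
    }
    if (!is.null(config$brain_mask)) {
      brain <- read_mask(config$brain_mask)
      res$maps <- fit_1tcm_voxelwise(image, idif_dense, brain, k2_grid,
                                     fit_window_s = config$fit_window_s)
    }
    res
  })

  files <- stage("write", {
    write_volume(seg$mask, out("carotid_mask.nii.gz"))
    write_volume(pvc$sleeve, out("sleeve_mask.nii.gz"))
    write_curve(seg$tac, out("tac_uncorrected.tsv"))
    write_curve(pvc$tissue_tac, out("tac_tissue.tsv"))
    write_curve(pvc$idif, out("idif.tsv"))
    f <- c("carotid_mask.nii.gz", "sleeve_mask.nii.gz",
           "tac_uncorrected.tsv", "tac_tissue.tsv", "idif.tsv")
    if (!is.null(bsif)) {
      write_curve(bsif$bsif, out("bsif.tsv"))
      f <- c(f, "bsif.tsv")
    }
    if (!is.null(kinetics$maps)) {
      vox <- image$voxel_size_mm
      write_volume(kinetics$maps$flow, out("cbf.nii.gz"), vox)
      write_volume(kinetics$maps$vd, out("vd.nii.gz"), vox)
      write_volume(kinetics$maps$k2, out("k2.nii.gz"), vox)
      f <- c(f, "cbf.nii.gz", "vd.nii.gz", "k2.nii.gz")
    }
    f
  })

  report <- list(
    software = paste0("widif ", as.character(utils::packageVersion("widif"))),
    config = config_as_list(config),
    segmentation = list(mask_voxels = sum(seg$mask$data),
                        reference_Bq_ml = seg$reference),
    pvc = list(alpha = pvc$factors$alpha, beta = pvc$factors$beta,
               kernel_fwhm_mm = pvc$factors$kernel_fwhm_mm,
               sleeve_voxels = sum(pvc$sleeve$data)),
    idif = list(peak_auc = auc(pvc$idif, min(pvc$idif$time_s), 60),
                tail_auc = auc(pvc$idif, 60, 300)),
    outputs = files
  )
  if (!is.null(bsif)) {
    met <- auc_metrics(idif_dense,
                       pet_curve(c(0, bsif$bsif$time_s),
                                 c(0, bsif$bsif$activity_Bq_ml)))
    report$bsif <- list(calibration_factor = bsif$calibration_factor,
                        delay_s = bsif$delay_s)
    report$idif_vs_bsif <- as.list(met)
  }
  if (!is.null(kinetics$gm_fit)) {
    report$gm_cbf <- as.list(glance(kinetics$gm_fit))
    if (!is.null(kinetics$gm_fit_bsif)) {
      report$gm_cbf_bsif <- as.list(glance(kinetics$gm_fit_bsif))
    }
  }
  if (!is.null(kinetics$maps)) {
    report$maps <- list(mean_cbf = mean(kinetics$maps$flow[kinetics$maps$flow > 0]))
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$voi <- unlist(cfg$voi)
  cfg[!vapply(cfg, is.null, logical(1))]
}
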