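# widif

Image-derived input functions (IDIFs) and cerebral blood flow (CBF)
quantification for dynamic ¹⁵O-water PET, in R.

## The problem

Quantitative CBF measurement with ¹⁵O-water PET traditionally requires
continuous arterial blood sampling to obtain the arterial input function —
invasive, error-prone and a major obstacle to clinical use. The carotid
arteries are visible in the scanner's field of view during the first pass of
the bolus, so in principle the input function can be read off the image
itself. In practice the carotids (5–6 mm diameter) sit at the resolution
limit of PET (≈2–2.6 mm FWHM), so a naive carotid time–activity curve (TAC)
underestimates the true blood concentration badly (spill-out) and is
contaminated by surrounding tissue (spill-in).

`widif` implements a stand-alone pipeline that needs nothing but the dynamic
scan:

1. **Carotid segmentation** — average the manually chosen early frames
   (tracer in the carotids, brain still empty), restrict to a neck VOI, and
   binarise at a percentage (default 42%) of the *median of per-slice maximum
   intensities*.
2. **Geometric partial-volume correction** — from the binary carotid mask
   `M` and a Gaussian resolution kernel `G` (default 2.1 mm FWHM) compute
   the spill-out fraction `α = Σ(G∗M · M)/ΣM` and spill-in fraction
   `β = Σ(G∗(1−M) · M)/ΣM`, estimate the surrounding-tissue TAC `C_T` from a
   sleeve mask (10-step minus 8-step dilation of `M`), and correct the
   carotid TAC `C_B^PET`:

   C_B(t) = ( C_B^PET(t) − β · C_T(t) ) / α

3. **Blood-curve conditioning** (for comparison against a blood-sampled
   input function): calibration to discrete well-counter samples, dispersion
   correction `c_true = c_meas + τ·dc/dt` (τ = 13 s), delay estimation, and
   resampling to the PET frame schedule.
4. **Kinetics** — basis-function fit of the single-tissue compartment model
   `dC_T/dt = F·C_a − (F/V_d)·C_T` over the first 5 min: precompute
   `B_i = C_a ⊗ e^{−k₂,i t}` on a log-spaced k₂ grid, solve the single
   linear coefficient F per k₂ by weighted least squares, keep the best.
   Regional fits and voxelwise parametric maps of F (= CBF for ¹⁵O-water),
   V_d and k₂.
5. **Evaluation** — peak (0–60 s) / tail (60–300 s) AUC metrics, a
   threshold × kernel grid search, Deming regression, Bland–Altman and
   CoV-of-differences agreement statistics.

Because clinical scans cannot ship with the package, `widif` also contains
two first-class synthetic phantoms: a dynamic brain phantom (two carotid-like
tubes carrying a gamma-variate bolus, grey/white-matter compartments obeying
single-tissue kinetics, Gaussian PSF blur, frame-duration-dependent noise)
and the classic static validation phantom (a 6-mm tube at 2.1 MBq/ml in a
20-cm water cylinder). Every stage of the pipeline is tested end-to-end
against phantom ground truth.

## Worked example

Simulate a scan, segment the carotids, correct the partial-volume effect and
quantify grey-matter CBF:

```r
library(widif)

phantom <- generate_dynamic_phantom(dynamic_phantom_spec(seed = 7))
scan <- phantom$image

voi <- voi_from_mask(phantom$truth$carotid_mask, margin = c(10, 10, 0))
seg <- segment_carotid(scan, segmentation_config(early_frames = 3:6,
                                                 threshold_pct = 42,
                                                 voi = voi))
seg$mask
#> <pet_mask> 96 x 96 x 48 voxels, 768 set

factors <- compute_pvc_factors(seg$mask, fwhm_mm = 2.1)
factors
#> <pvc_factors> alpha = 0.7467, beta = 0.2533 (kernel 2.10 mm FWHM)

sleeve <- sleeve_tissue_mask(seg$mask, inner = 8, outer = 10)
idif <- correct_blood_curve(seg$tac, extract_tac(scan, sleeve), factors)

auc_metrics(idif, resample_to_frames(phantom$truth$input, scan$schedule))
#>   peak_auc tail_auc peak_bias_pct tail_bias_pct
#> 1  2606913  2488613          -4.7          -4.7

fit <- fit_1tcm(extract_tac(scan, phantom$truth$gm_mask),
                make_basis(phantom$truth$input, scan$schedule))
fit
#> <onetcm_fit> F = 0.616 ml/cm^3/min, Vd = 0.867 ml/cm^3, k2 = 0.711 /min
#>   weighted RSS 1.422e+05 over 20 frames
```

Reading: only 74.7% of the true carotid signal survives blurring inside the
mask (`alpha`), and a quarter of the in-mask measurement would come from
surroundings at unit concentration (`beta`). After correction the IDIF's
peak and tail areas sit within 5% of the simulated arterial truth, and the
grey-matter perfusion estimate (0.616 ml/cm³/min) recovers the simulated
0.64 ml/cm³/min to within 4% despite frame noise and resolution blur.

`tidy(fit)` / `glance(fit)` give broom-style summaries, `autoplot()` works
on curves, fits and grid-search results, and `run_pipeline(run_config(...))`
(or the thin CLI in `inst/cli/widif.R`) drives the whole chain from NIfTI +
JSON-sidecar files to a JSON report.

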