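---
title: "Image-derived input functions for dynamic water PET: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-derived input functions for dynamic water PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science inside `widif`: the models it
implements, the tunable parameters and their defaults, what the synthetic
phantoms do and do not emulate, and the numerical and design choices that
were genuinely open.

## 1. The measurement problem

A dynamic ¹⁵O-water PET scan records activity concentration (Bq/ml) in every
voxel across frames of variable duration. Quantifying cerebral blood flow
requires the arterial input function \(C_a(t)\). The carotid arteries carry
that signal through the field of view, but at 5–6 mm diameter they are
barely larger than the scanner's point-spread function (PSF), so a raw
carotid time–activity curve (TAC) suffers severe partial-volume effects:
signal spills out of the vessel (underestimation) and surrounding-tissue
signal spills in (late-time contamination).

## 2. Carotid segmentation

Early in the scan the bolus fills the carotids while the brain is still
empty. The user selects those frames by inspection (typically within the
first 30 s; `suggest_early_frames()` offers an advisory heuristic but the
choice is deliberately manual — visibility criteria cannot be encoded
robustly). The selected frames are averaged **unweighted**; during the early
part of the standard 26-frame schedule all frames last 5 s, so unweighted
and duration-weighted averaging coincide.

The average is restricted to the inferior third of the axial field of view
(`crop_neck()`) and to a hand-drawn box VOI around the carotids. Within the
VOI, the maximum intensity of each axial slice is tabulated and the *median*
of these per-slice maxima is the reference value; the binary carotid mask is
every VOI voxel strictly above `threshold_pct`% of that reference
(default 42%). Conventions worth noting:

* per-slice maxima are taken *within the VOI* (more robust to other hot
  structures than whole-slice maxima; the alternative reading of the
  procedure differs only when hot structures share the slice);
* an even slice count takes the mean of the two central maxima;
* ties at exactly the threshold are excluded (strict `>`); this matters only
  for degenerate synthetic inputs;
* no connected-component filtering by default; `segment_carotid()` exposes
  an optional minimum-component-size filter for noisy data.

The threshold's theoretical anchor: for a homogeneous object comfortably
larger than the PSF, thresholding a blurred image at ~41% of its maximum
recovers the true object volume; 42% is the empirically optimal operating
point, and `grid_search()` reproduces that optimisation over thresholds
(38–46%) and kernel widths (2.0–2.4 mm).

## 3. Spill-out, spill-in, and the corrected blood curve

With mask \(M\) and Gaussian kernel \(G\) (FWHM default 2.1 mm,
\(\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}\)):

\[
\alpha = \frac{\sum (G*M)\,M}{\sum M}, \qquad
\beta  = \frac{\sum (G*(1-M))\,M}{\sum M}, \qquad
C_B(t) = \frac{C_B^{PET}(t) - \beta\, C_T(t)}{\alpha}.
\]

\(C_T\) is the surrounding-tissue TAC measured in a sleeve: the 10-step
dilation of the mask minus its 8-step dilation — far enough out to escape
carotid spill-over, close enough to stay in the neck.

Numerical choices:

* **Boundary mode is replicate** (constant-preserving). This makes
  \(\alpha + \beta = 1\) hold to machine precision for any mask — smoothing
  is linear and \(M + (1-M) = 1\) is preserved — and avoids the edge bias
  that zero-padding would introduce. Masks touching the grid boundary still
  deviate; carotid masks are interior in practice.
* **Kernel truncation at 4σ** per axis, renormalised; affects α below 1e-6.
* **Dilation counts voxel steps**, 6-connected by default (configurable to
  18/26). On the anisotropic scanner grid 8–10 voxel steps are ≈7.8–9.8 mm
  in-plane but ≈22–28 mm axially; the voxel-step reading follows the
  method's own description, and the sleeve TAC is insensitive to the choice
  for smooth backgrounds.
* α and β are computed on the full grid, with the same kernel used for both
  factors and (in validation) for the simulated PSF.

The headline self-consistency, asserted in the tests: if the measured image
is *exactly* \(C_B(t)\,(G*M) + C_T(t)\,(G*(1-M))\) with uniform tissue
outside the mask, the correction returns \(C_B(t)\) at every frame to
machine precision.

## 4. Blood-sampler conditioning

For comparison against a blood-sampled input function the raw sampler curve
is (i) scaled by the mean of per-sample ratios against discrete well-counter
samples — the mean-of-ratios convention rather than a regression, because
only two late samples are typical; (ii) dispersion-corrected with the
monoexponential model \(c_{true} = c_{meas} + \tau\,\dot c_{meas}\), τ
defaulting to 13 s (≈8 s line + ≈5 s body dispersion). The derivative is a
3-point central difference after a 3-sample moving average, since the τ·dc/dt
term amplifies noise at the sampler's ~1-s resolution; (iii) delay-corrected
by a grid search (−5…+15 s, 0.5-s steps) aligning the peak-normalised curve
to a reference TAC over the first minute — positive delay means the sampler
lags the brain, and the curve is shifted earlier; (iv) frame-resampled by
averaging the linear interpolant over each frame interval, stamped at frame
mid-times. IDIFs receive *no* delay or dispersion correction — they are
measured at the brain's doorstep.

TAC time stamps throughout the package are frame **mid-times** (start +
duration/2); the alternative (frame starts) is not supported.

## 5. Single-tissue compartment kinetics

¹⁵O-water is freely diffusible with extraction ≈ 1, so
\(dC_T/dt = F C_a - (F/V_d) C_T\), i.e. \(K_1 \approx F\) (CBF) and
\(k_2 = F/V_d\). The basis-function linearisation precomputes
\(B_i(t) = C_a \otimes e^{-k_{2,i} t}\) by *exact* convolution of the
piecewise-linear input interpolant on a 0.25-s grid (a recursive
exponential-update scheme, no quadrature error beyond the interpolant),
frame-averages each basis curve, and solves the one-parameter weighted least
squares \(C_T \approx F B_i\) per grid point, keeping the minimal weighted
RSS.

Declared defaults (the reference implementation's internals are not public,
so these are this package's own choices):

* **k₂ grid**: 100 log-spaced points in [0.01, 3] min⁻¹ — covers CBF
  0.1–2 ml/cm³/min at V_d 0.3–1.2 ml/cm³ with ≈6% spacing, so V_d is
  quantised at about that resolution while F, which is fit linearly, is
  recovered to better than 2% on noise-free data (asserted in the tests);
* **weights**: frame durations;
* **fit window**: frames with mid-time ≤ 300 s (the first five minutes,
  where the water model is most valid);
* **units**: per-second internally, ml/cm³/min and min⁻¹ externally;
* negative fitted F is clamped to zero and flagged;
* no arterial blood-volume term (the single-tissue statement of the model);
  adding one is an explicit non-goal.

Voxelwise fitting reuses one shared basis set and vectorises the per-k₂
least squares across all mask voxels.

## 6. The synthetic phantoms

**Dynamic brain phantom** (`dynamic_phantom_spec()`): 96 × 96 × 48 voxels of
0.98 × 0.98 × 2.79 mm (the scanner grid, cropped to keep runtime small); two
5.5-mm tubes in the neck third carrying the arterial model; an ellipsoidal
brain strictly above the sleeve's reach with a grey-matter shell
(F = 0.64 ml/cm³/min, V_d = 0.9 ml/cm³ — the baseline GM operating point)
and white-matter core (F = 0.20, V_d = 0.8; V_d truth values are not
reported for patients and are set inside the physiological range). The
arterial model is a peak-normalised gamma-variate
\(A u^k e^{k(1-u)}\), \(u = (t-t_0)/s\), plus a recirculation tail
\(f A (1-e^{-u}) e^{-\lambda (t-t_0)}\); defaults A = 1e5 Bq/ml, t₀ = 10 s,
k = 3, s = 15 s (peak at 25 s — note the gamma-variate peaks at \(t_0+s\)),
f = 0.15, λ = 0.002 s⁻¹, shaped to mimic a 10-ml/10-s bolus with saline
flush. Frames follow the standard 26-frame schedule; the simulation PSF is
2.3 mm FWHM (the scanner's capillary-based estimate of 2.6 mm is known to
overstate the true resolution, so the phantom sits below it, deliberately
*not* equal to the 2.1-mm correction kernel); noise is zero-mean Gaussian
with SD \(= \eta \sqrt{\max(v,0)/\Delta t}\) per frame (η = 20, ≈3% of the
bolus peak on a 5-s frame — no quantitative noise level is published for
penalised reconstructions, so η was calibrated once to visually realistic
TAC jitter and frozen). Tube-boundary partial volume is handled by ≥4×
in-plane supersampling of the analytic indicator before blurring.

**Static tube phantom** (`static_phantom_spec()`): 6-mm tube at 2.1 MBq/ml
in a 20-cm zero-activity water cylinder over ≈5 cm of axial extent, same
voxel grid, PSF default 2.1 mm (matched to the correction kernel, the
validation condition), noise-free by default.

What the phantoms do **not** emulate: reconstruction physics (the penalised
reconstruction itself, scatter, randoms, attenuation, Gibbs/ringing from
resolution recovery), patient motion, spatially varying or non-Gaussian
PSFs, real neck anatomy (the tube surroundings are empty rather than
perfused soft tissue — which makes the sleeve term exactly zero in the
phantoms), curved or tapering vessels, and decay (images are taken as
decay-corrected). Passing phantom tests therefore demonstrates the
*internal* consistency and numerical correctness of the chain, not clinical
accuracy on scanner data.

## 7. Known behaviour and limitations

* On the noise-free static phantom at the fixed 42%/2.1-mm operating point
  the recovered concentration is biased by about −1% — the residual of
  correcting a fractional-occupancy object with a binary-mask α. The
  residual depends strongly on the vessel's sub-voxel position (≈−1% for a
  voxel-centred tube, several per cent off-centre), which is the digital
  analogue of the method's sensitivity to carotid size and position.
* The discrete threshold makes mask volume a step function of the threshold:
  adjacent grid-search cells can share identical masks, and small objects
  can jump by whole voxel rings.
* The sleeve assumes surroundings homogeneous at its radius; it cannot
  represent a hot structure directly adjacent to the carotid.
* Dispersion correction is a derivative-based inverse filter; at 1-s
  sampling the bolus AUC round-trips to within 2%, but heavier smoothing
  would be needed for noisier samplers.
* Problem sizes in the test-suite and validation runs: 96 × 96 × 48 dynamic
  grids, a 64 × 64 × 36 grid for grid-search and voxelwise checks, and the
  full 213 × 213 × 18 static phantom — chosen so a complete run stays
  comfortably interactive on a single CPU while keeping all objects at the
  scanner's native voxel size.

## 8. Reproducibility

All randomness (phantom noise) flows from a single integer seed carried in
the phantom spec; analysis stages are deterministic. `run_pipeline()` echoes
every resolved parameter into its JSON report, and
`scripts/acceptance.R --seed N --out f.json` regenerates the static-phantom
validation number from scratch.
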