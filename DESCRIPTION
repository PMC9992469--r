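Package: widif
Title: Image-Derived Input Functions and Blood-Flow Quantification for Dynamic Water PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive an arterial input function directly from dynamic
    oxygen-15 water PET images: carotid segmentation of early frames by
    thresholding at a percentage of the median of per-slice maxima, geometric
    spill-in/spill-out partial-volume correction of the carotid time-activity
    curve, conditioning of blood-sampler curves (calibration, delay and
    dispersion correction, resampling to frame times), and cerebral blood flow
    estimation with a basis-function implementation of the single-tissue
    compartment model. Includes synthetic digital phantoms (dynamic brain
    phantom and static tube phantom) so the whole pipeline can be exercised
    and validated without scanner data, plus AUC, orthogonal-regression and
    Bland-Altman agreement statistics and a threshold-by-kernel grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
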