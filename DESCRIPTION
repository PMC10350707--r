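Package: archpulse
Title: Quantification of Cardiac-Pulsatility-Induced Vessel Motion,
    Geometry and Diameter Dynamics from ECG-Gated CT Deformation Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic analysis of retrospectively ECG-gated CT:
    anatomical points are tracked through ten per-phase displacement vector
    fields to obtain per-axis motion amplitudes (pulsatility) and traveled
    pathlength; vessel centerlines resampled at 1 mm are smoothed with a
    Savitzky-Golay filter (polynomial order 4, window 33) to obtain length,
    tortuosity index and numerical curvature together with their
    cardiac-pulsatility-induced changes over the cycle; perpendicular lumen
    diameter pairs are measured at 1 cm centerline levels from a surface mesh
    or binary mask and followed across phases to quantify pulsatile
    expansion. An analytic vessel-phantom generator (arcs, helices, straight
    tubes with translation, radial-pulsation and bending motion modes)
    provides closed-form ground truth so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
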