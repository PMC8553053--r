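Package: ecarecon
Title: Enhancement-Constrained Acceleration for Simulated Breast DCE-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for highly accelerated
    dynamic contrast-enhanced (DCE) breast MRI. Provides continuous-time
    digital phantoms (Parker population arterial input function in vessels,
    truncated-exponential enhancement in lesions, spoiled gradient-echo
    signal model), a time-tagged virtual k-space scanner with the UnWRAP
    (Undersampling With Repeated Advancing Phase) Cartesian ordering and
    calibrated Gaussian k-space noise, an enhancement-constrained
    acceleration (ECA) reconstruction that minimizes a quadratic temporal
    smoothness penalty subject to exact agreement with time-partitioned
    k-space measurements, a sweep-by-sweep inverse-FFT baseline, and kinetic
    analysis of the reconstructions (bolus arrival time, initial enhancement
    slope, paired error-ratio statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
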