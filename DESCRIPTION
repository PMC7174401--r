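Package: ptmr
Title: Particle-Tracking Microrheology of Chromatin Granules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Passive particle-tracking microrheology for time-lapse
    phase-contrast imaging of chromatin granules in isolated nuclei.
    Detects diffraction-limited granules as symmetric 2D-Gaussian spots,
    links them across frames with scale- and rotation-invariant
    gradient descriptors, removes collective drift by intensity-weighted
    centre-of-mass subtraction and SVD rigid alignment, computes
    time-averaged mean squared displacements, estimates effective
    diffusivities and apparent viscosities via the Stokes-Einstein
    relation, derives frequency-dependent viscoelastic moduli through
    the analytic (Mason) approximation to the generalized
    Stokes-Einstein relation, summarises each nucleus as a Kelvin-Voigt
    body, and compares groups of nuclei with non-parametric tests. A
    synthetic-data module simulates free, confined (Ornstein-Uhlenbeck)
    and drifting granule motion and renders it as noisy image stacks so
    the whole pipeline is testable end to end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    tiff,
    minpack.lm,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
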