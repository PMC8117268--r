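Package: flumen
Title: False-Lumen Hemodynamics from 4D Flow Cardiovascular MRI
Version: 0.1.0
Authors@R:
    person("flumen", "maintainers", email = "flumen@example.org", role = c("aut", "cre"))
Description: Quantifies false-lumen pressurization in aortic dissection from
    time-resolved three-dimensional phase-contrast (4D flow) velocity fields.
    Implements the false lumen ejection fraction (FLEF), the maximum systolic
    deceleration rate (MSDR), and virtual work-energy relative pressure
    (vWERP) estimation with a divergence-free virtual field computed by a
    staggered-grid Stokes solve, together with a synthetic dissected-vessel
    phantom generator with analytic ground truth, segmentation/plane
    perturbation machinery for reproducibility studies, and the cohort-level
    statistical layer (growth-rate outcome, normality-routed group
    comparisons, robust-standard-error regression, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
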