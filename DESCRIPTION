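Package: neuronsurv
Title: Longitudinal Single-Neuron Survival Analysis from Two-Channel
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal survival analysis of individual
    neurons imaged by automated two-channel fluorescence microscopy.
    Simulates experiments in which neuron death times follow a
    programmable proportional-hazards model with group effects and a
    time-varying stress-reporter covariate, rendering them as noisy
    two-channel image stacks with exact ground truth; segments and
    tracks neurons by centroid linking, scoring death as disappearance
    and quantifying background-subtracted red/green fluorescence on
    red-channel masks; and fits the statistical pipeline used for such
    data: Nelson-Aalen cumulative hazards, Cox proportional-hazards
    models with well-level cluster-robust variance and plate-level
    stratification, Schoenfeld residual diagnostics, reporter
    normalization, and quartile-binned reporter-hazard models with left
    truncation at the reporter reference time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    survival,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
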