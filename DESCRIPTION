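Package: octaflow
Title: Retinal Vessel Morphometry and Doppler OCT Blood Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal vascular morphology and haemodynamics from
    en-face OCT angiography (OCTA) images and phase-resolved Doppler OCT
    volumes. Provides k-means vessel segmentation with centerline extraction
    between bifurcation points, the vessel tortuosity index (VTI), box-counting
    local fractal dimension maps with vessel-density / inter-vessel-spacing
    partitions, total retinal blood flow (TRBF) from Doppler phase shifts, and
    a cohort statistics layer (group tests, power, and variance-components
    mixed models with intra-subject eye correlation). Includes synthetic
    generators for vessel images, branching trees, Poiseuille flow phantoms,
    and two-group cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
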