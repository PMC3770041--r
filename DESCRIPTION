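Package: gliomorph
Title: Nuclear Morphometry for Grading Diffusely Infiltrating Gliomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, measurement and statistical analysis of nuclear
    morphometry in diffusely infiltrating gliomas. Generates seeded,
    ground-truthed labeled nucleus fields for control, low-grade and
    high-grade cohorts; measures per-nucleus major/minor axis, area,
    perimeter and roundness and per-field nuclear density and percent
    total nuclear area from calibrated label images; and reproduces the
    group-level statistical layer (summary tables, pooled-variance
    Student t-tests, grade correlations and Gaussian area-distribution
    overlays) used to separate tumour grades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
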