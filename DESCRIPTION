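Package: stircell
Title: Shear Environment, Growth Kinetics and Cell Morphology for Stirred-Tank Suspension Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing ex vivo suspension-cell expansion in small
    unbaffled stirred-tank bioreactors. Computes the hydrodynamic shear
    environment (impeller Reynolds number, Nagata power number for unbaffled
    paddle impellers, specific energy dissipation, maximum shear stress,
    integrated shear factor, Kolmogorov eddy length) from vessel geometry,
    fluid properties and agitation rate; fits batch exponential growth and
    metabolite mass-balance kinetics with explicit handling of partial
    medium-exchange events; quantifies cell roundness and round-cell
    frequency from grayscale microscopy images; and generates synthetic
    culture time series and cell images with known ground truth for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
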