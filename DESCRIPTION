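Package: spherotrack
Title: Morphometric Analysis of Matrix-Embedded Tumor Spheroids
Version: 0.1.0
Authors@R:
    person("Spherotrack", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for evaluating drug response in 3D
    matrix-embedded tumor spheroids from time-series brightfield images.
    Segments one spheroid per well, extracts a sub-pixel boundary contour,
    and computes isoperimetric shape descriptors (excess perimeter index,
    roughness), equivalent diameter and spherical volume, then aggregates
    wells into relative tumor volume (RTV), tumor growth inhibition (TGI),
    normalized Alamar Blue viability, invasiveness classification, and
    four-parameter logistic dose-response summaries under normoxia and
    hypoxia. Includes a synthetic phantom generator with analytic
    ground-truth boundaries so the entire pipeline is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr,
    yaml
Config/testthat/edition: 3
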