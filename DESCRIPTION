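Package: skelphen
Title: Quantitative Skeletal Phenotyping of Mouse Bone
Version: 0.1.0
Authors@R:
    person("Skeletal", "Phenotyping", email = "skelphen@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantitative skeletal phenotyping of
    knockout mouse models. Extracts yield load, maximum load, fracture load
    and stiffness from destructive three-point-bend and compression
    load-displacement curves; fits wild-type reference regressions of
    biomechanical parameters on bone mineral content and scores mutant
    groups in residual-SD units (bone quality analysis); calibrates
    gray-level images (X-ray microradiography, quantitative BSE-SEM)
    against imaging standards and summarizes mineralization-density
    distributions; compares density distributions with a percent-scaled
    two-sample Kolmogorov-Smirnov test; computes ASBMR static and dynamic
    histomorphometry parameters and growth-plate morphometry; and provides
    delta-delta-CT expression quantitation, group-comparison wrappers and
    CV-based power calculations. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
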