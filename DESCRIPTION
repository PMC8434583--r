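Package: ringlap
Title: Finite-Dimensions Optimization of Concentric Ring Electrodes for
    Surface Laplacian Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing tripolar concentric ring electrodes (TCREs)
    under the finite dimensions model. Derives surface-Laplacian estimation
    weights and truncation-term coefficients in exact rational arithmetic,
    exhaustively enumerates and ranks all admissible electrode geometries for
    a given outer radius, and validates competing configurations against the
    closed-form field of a current dipole in a homogeneous half-space on a
    dense planar mesh, reporting sensitivity, spatial-resolution, and error
    measures (maximum Laplacian amplitude, normalized spatial gradient,
    relative error, normalized maximum error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
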