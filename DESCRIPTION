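Package: microwss
Title: Cell-Resolved Microvascular Blood Flow and Wall Shear Stress Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale, cell-resolved simulation and quantification of wall
    shear stress (WSS) and its surface gradient (WSSG) in microvessels.
    Generates synthetic microvessel geometries (straight and tortuous tubes,
    bifurcations, convergences, small Strahler-ordered networks) with
    triangulated walls and signed-distance fields; models red blood cells as
    closed hyperelastic membranes (Skalak in-plane law plus Helfrich bending)
    with finite-element force densities; advances unsteady Stokes flow on a
    staggered Cartesian grid with an immersed-boundary coupling for cells and
    ghost-node no-slip walls; and extracts per-vertex wall traction in a local
    flow-aligned frame, axial and circumferential WSS gradients, region-of-
    interest averages, temporal RMS statistics, red-cell influence ratios, and
    bifurcation phase-separation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
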