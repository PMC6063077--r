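Package: tracheidr
Title: Process-Based Simulation of Conifer Tracheid Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A process-based model of xylem cell (tracheid) differentiation in
    conifers. Each cell is described in cross-section by three state variables
    (cell area, wall area, lignified wall area) whose coupled ordinary
    differential equations capture radial enlargement, secondary-wall
    deposition and lignification, all driven by the sugar availability at the
    cell's position in the tree ring. The package integrates the system with a
    fixed-step classical Runge-Kutta scheme, assembles whole-ring
    tracheidograms, classifies earlywood and latewood by Mork's index,
    calibrates free parameters against observed tracheidograms by Nelder-Mead
    least squares, and generates synthetic observations with known ground
    truth for testing the calibration machinery. Species parameter sets for
    Pinus cembra, Picea abies, Larix decidua and Picea mariana are bundled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
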