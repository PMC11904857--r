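Package: cmquant
Title: Quantification of Cardiomyocyte Electrophysiology, Calcium
    Transients and Sarcomere Morphometry
Version: 0.1.0
Authors@R:
    person("cmquant", "developers", email = "cmquant@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for phenotyping stem-cell-derived
    cardiomyocytes: voltage-clamp sodium current analysis (peak
    current density, current-voltage relations, conductance transform,
    Boltzmann fits of steady-state activation and inactivation),
    current-clamp action potential parameterization (APA, APD30/50/90,
    upstroke velocity), paced Fura-2 calcium transient parameterization
    (amplitude, time-to-peak and recovery fractions, velocities, areas
    under the curve), intensity-profile morphometry of striated
    two-channel images (actin shift, Z-disk width, band lengths,
    normalized intensity), and nonparametric two-group statistics
    (Mann-Whitney U). Includes synthetic-data generators with known
    ground truth for every modality so the whole pipeline is testable
    without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
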