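Package: cobioleach
Title: Cascade Chemostat Modelling and Leach-Yield Analysis for
    Co-Bioleaching of Pyrite Tailings and E-Waste
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for co-bioleaching experiments in
    which pyrite flotation tailings and ground printed circuit board (PCB)
    dust are leached in a two-reactor chemostat cascade. Implements the
    cascade growth model (closed-form and numerical solutions, steady states,
    growth-regime classification), the stepwise material-balance model for
    in-reactor PCB concentration, specific growth-rate estimation from cell
    count time series, leaching stoichiometry checks and acid/iron budgets,
    control-corrected metal leach yields, batch-mode process indicators
    (threshold crossings, ferrous-iron depletion, lag phase), and
    community-exposure correlation for genus relative-abundance tables.
    Includes a seeded synthetic-data generator emulating batch and continuous
    runs so every analysis step is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
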