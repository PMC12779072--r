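Package: shieldbio
Title: Photon Shielding, Docking Thermodynamics and Antimicrobial
    Statistics for Small-Molecule Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the computational
    characterization of small-molecule drug candidates along three axes:
    gamma-ray shielding (mixture-rule mass attenuation coefficients,
    linear attenuation, half-value layer, mean free path, equivalent
    atomic number and geometric-progression buildup factors), docking
    thermodynamics (binding free energy to inhibition constant
    conversion and MM/PBSA component aggregation), and antimicrobial
    activity statistics (two-fold dilution MIC validation, one-way
    ANOVA and Tukey HSD). Ships reference tables for a series of six
    bis-piperazine Schiff-base candidates and a synthetic-data module
    so every stage is testable against closed-form oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
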