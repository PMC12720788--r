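Package: hdxdelta
Title: Differential Analysis of Hydrogen-Deuterium Exchange Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Peptide-level analysis of hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) experiments that contrast protein variants and
    ligand-bound states. Provides readers and writers for long-format uptake
    summary tables, pooled replicate-variability estimation and Wood's-plot
    significance calls for differential deuterium uptake, one-exponential
    uptake-curve fitting with EX2 back-calculation of opening equilibria,
    quadratic 1:1 binding-occupancy planning for labeling conditions, and a
    residue-level Linderstrom-Lang two-state exchange simulator with known
    ground truth for method validation. Results are tidy tibbles throughout,
    with ggplot2 graphics and broom-style tidiers for fitted objects.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
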