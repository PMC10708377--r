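Package: pisawheel
Title: PISA-Wheel Simulation, Helix Tilt Fitting and Chemical Shift
    Perturbation Analysis for Oriented-Sample NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and fitting tools for oriented-sample
    solid-state NMR of membrane-protein helices, built around the
    syndecan-4 transmembrane construct. Simulates PISA (polarity index
    slanted angle) wheel patterns -- per-residue 15N chemical shift and
    1H-15N dipolar coupling for an ideal tilted helix in magnetically
    aligned bicelles -- fits helix tilt and azimuthal rotation from 2D
    separated-local-field peak lists (including a two-wheel dimer fit),
    and maps ligand binding by chemical shift perturbation between HSQC
    peak lists. A synthetic peak-list generator makes every stage
    testable without spectrometer data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
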