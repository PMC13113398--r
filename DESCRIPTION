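Package: navclamp
Title: Simulation and Analysis of Voltage-Gated Sodium Channel Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded simulator of voltage-clamp and current-clamp recordings
    from a Boltzmann-gated sodium conductance, together with the analysis chain
    used in scorpion-toxin electrophysiology: peak extraction, conductance
    transform, Boltzmann steady-state activation/inactivation fits, full
    Boltzmann I-V maximal-conductance estimation, window-current area,
    biexponential decay kinetics, recovery from inactivation, spike detection
    and mean firing frequency, paired statistics with multiple-testing
    adjustment, and post-docking structural interface analysis (residue
    contacts, hydrogen bonds, salt bridges, replicate docking-score
    statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    minpack.lm,
    bio3d,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
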