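Package: kaiabc
Title: Simulation of the KaiABC Post-Translational Circadian Oscillator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid stochastic-deterministic simulator of an ensemble of KaiC
    hexamers coupled through KaiA sequestration. Each hexamer carries a
    continuous phosphorylation level, mean-field KaiA/KaiB binding
    probabilities, a two-state structural order parameter in quasi-equilibrium,
    and stochastic nucleotide (ATP/ADP) states in the six CI domains. The
    package provides temperature rules (Arrhenius scaling, thermal attenuation
    of the reaction-structure coupling, thermally activated KaiB fold switch,
    temperature-insensitive ATPase), protocol drivers for feedback-strength
    scans, temperature scans and Q10, phase-response curves to temperature
    steps and ADP pulses, ATPase scaling scans, and desynchronization assays,
    plus trajectory analysis (period, amplitude, circadian time, phase shift,
    synchrony index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
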