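Package: ionshift
Title: Compartmental CA1 Pyramidal-Neuron Simulation with Full Ionic Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Biophysically detailed simulation of hippocampal CA1 pyramidal
    neurons with dynamic intra- and extracellular Na+, K+, Cl- and Ca2+
    concentrations, fixed bicarbonate, chloride/potassium cotransport (KCC2,
    NKCC1), Na/K-ATPase and calcium handling, glial potassium buffering,
    longitudinal diffusion, Markov-scheme fast sodium and GABA-A receptor
    kinetics with a 1:4 bicarbonate:chloride permeability split, and an
    implicit-Euler cable solver on branched morphologies. Includes the
    high-frequency GABAergic stimulation protocols used to study
    GABA-A-mediated excitation, a rest-state calibration algorithm, SWC
    morphology input, and synthetic morphology generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
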