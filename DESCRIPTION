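Package: bvrsim
Title: Stochastic Ventricular Myocyte Simulation and Beat-to-Beat
    Repolarization Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates action potentials of a reduced canine-like
    ventricular myocyte in which thirteen major ionic currents and
    calcium-handling fluxes can each be switched between deterministic,
    stochastic Markov channel-gating, and Langevin (stochastic
    differential equation) formulations. Provides pacing and perturbation
    protocols (fixed cycle-length and fixed diastolic-interval pacing,
    constant current injection, membrane-potential noise calibration,
    action-potential morphology presets), condition modifiers mimicking
    long-QT syndromes 1-3, beta-adrenergic stimulation and partial
    sodium-potassium pump inhibition, electrically coupled cell pairs and
    one-dimensional strands, multi-domain calcium handling with
    diffusional exchange, and a population-of-models sensitivity
    analysis. Quantifies beat-to-beat variability of repolarization from
    per-beat action-potential durations at 90 percent repolarization via
    short- and long-term variability, Poincare analysis, coefficient of
    variation, membrane-current fluctuation profiles and exponential
    duration-variability fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
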