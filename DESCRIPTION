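Package: mpsr
Title: Stochastic Damage Dynamics and Lifespan Analysis for Starving Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing membrane-damage dynamics and death timing in
    starving single cells imaged in mother-machine microfluidic devices. The
    package implements the membrane-potential saturating-repair (MP-SR)
    stochastic model of damage accumulation: model definition with
    quasi-steady-state (Boltzmann) damage densities, Euler-Maruyama trajectory
    simulation with first-passage death times and escape-rate hazards, a
    synthetic cohort generator producing propidium-iodide-like fluorescence
    traces, extraction of windowed uptake rates and damage from fluorescence,
    cross-sectional cohort statistics with bootstrap errors, survival and
    Gompertz-slope analysis, marginal distribution fitting across candidate
    families including the generalized beta distribution of the second kind,
    and maximum-likelihood fitting of the model by simulated or Gaussian
    transition likelihoods with an interval-halving grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
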