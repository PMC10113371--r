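# mpsr

Stochastic damage dynamics and the timing of cell death in starving single
cells.

Genetically identical bacteria starved in a microfluidic mother machine die
at very different times. This package implements the analysis chain for one
explanation of that spread: membrane damage — measured as the log of the
normalized propidium-iodide (PI) uptake rate, `X = ln(uptake)` in units of
kBT — follows the **membrane-potential saturating-repair (MP-SR)** stochastic
model

    dX/dt = eta0 + eta * t  -  beta * e^{aX} / (e^{aX} + e^{a*kappa})  +  sqrt(2*sigma) * xi

Damage production rises linearly with age while removal saturates in damage,
so noise is amplified as cells age; death is the first passage of `X` across
a threshold `x_c`. The frozen-age stationary density is the Boltzmann form
`P(X) ~ exp(-U(X,t)/sigma)`, which on the uptake scale is exactly a
generalized beta distribution of the second kind (GB2) — the bridge between
cross-sectional distribution fitting and the dynamical model.

The package provides, as plain R functions:

- **Model core** — parameters, drift, saturating removal fraction, potential
  and quasi-steady density (`mpsr_params()`, `mpsr_drift()`,
  `removal_fraction()`, `qss_density()`).
- **Simulation** — Euler-Maruyama ensembles with per-cell RNG streams,
  first-passage death times, empirical and analytic escape-rate hazards
  (`simulate_paths()`, `sample_first_passage()`, `kramers_hazard()`).
- **Synthetic cohorts** — mother-machine-like fluorescence traces driven by
  the latent damage process, with measurement noise, a high-initial-damage
  subpopulation, covariates and a truth ledger (`cohort_config()`,
  `generate_cohort()`, `write_truth()`).
- **Extraction** — normalization, adaptive Wiener smoothing, windowed
  derivative estimation of uptake/damage, death calling
  (`extract_cohort()`).
- **Cohort statistics** — cross-sectional mean/SD/CV/skewness with cell
  bootstraps, damage autocorrelation, initial-condition analysis,
  remaining-lifespan alignment, twilight (`cross_sectional_stats()`,
  `initial_condition_analysis()`, `twilight()`).
- **Survival** — Kaplan-Meier curves, cumulative hazard, Gompertz slopes,
  two-cohort comparisons (`survival_curves()`, `gompertz_slope()`,
  `compare_cohorts()`).
- **Distribution fitting** — 15 candidate families ranked by
  Kolmogorov-Smirnov distance, GB2 density/CDF/sampler, and the GB2-to-MP-SR
  parameter mapping (`fit_marginal()`, `dgb2()`, `gb2_to_mpsr()`).
- **Inference** — maximum-likelihood fitting of the six model parameters by
  simulated (`sim_kde`) or Gaussian (`euler_gauss`) transition likelihoods
  with an interval-halving grid search and bootstrap convergence checks
  (`fit_mpsr()`, `transition_loglik()`).
- **Pipeline** — an end-to-end driver with manifests, checksums and resume
  (`run_pipeline()`).

The `analysis/` directory holds the numbered workflow scripts
(`01_generate_cohort.R` ... `07_stress_mutant_prediction.R`) that run the
full study over the package functions and write their tables under
`results/`.

## Worked example

Simulate a cohort from the fitted wild-type parameters, extract damage from
the fluorescence traces, and look at survival:

```r
library(mpsr)

cfg <- cohort_config(n_cells = 200, seed = 1)   # 6% noise, hourly, 120 h
cohort <- generate_cohort(cfg)
ex <- extract_cohort(cohort$traces, cfg$rule)
sc <- survival_curves(ex$lifespans$lifespan_h, ex$lifespans$censored,
                      n_boot = 200, seed = 2)
print(sc)
#> Survival curve: 200 deaths, 0 censored
#>   mean lifespan 75.2 h (CV 0.23); 5/50/95% quantiles 50/77/100 h

gompertz_slope(sc, n_boot = 200, seed = 3)$slope
#> [1] 0.06507102
```

A mean lifespan of ~75 h with CV ~0.23 and a positive Gompertz slope of
~0.06/h: the cohort dies with the sigmoidal survival curve and exponentially
rising death risk characteristic of starving *E. coli*, even though every
cell shares one parameter set — lifespan differences here are purely noise
amplified by saturating repair. Fitting the model back from damage
trajectories:

```r
obs <- simulate_paths(wildtype_params(), n = 200, t0 = 20, t1 = 80,
                      dt = 0.05, seed = 4)
hourly <- which(obs$times %% 1 == 0)
damage <- data.frame(cell_id = rep(sprintf("c%03d", 1:200),
                                   each = length(hourly)),
                     time_h = rep(obs$times[hourly], 200),
                     damage_kBT = as.vector(t(obs$paths[, hourly])))
fit <- fit_mpsr(transition_table(damage), fit_config(seed = 5))
print(fit$theta_hat)
```

The noise intensity `sigma` and production slope `eta` come back within a
few percent; the four removal-curve parameters `(beta, a, kappa, eta0)` are
constrained jointly but sit on a flat likelihood ridge at this problem size
— see the methods vignette (`vignettes/damage-dynamics-methods.Rmd`) for the
identifiability analysis.

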