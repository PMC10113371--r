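---
title: "Methods: the MP-SR damage model and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MP-SR damage model and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsr)
```

## The model

Starving, non-growing single cells die at widely different times even though
they are genetically identical and share one environment. The quantity this
package tracks is membrane damage, measured through the uptake rate of
propidium iodide (PI): PI enters only when membrane integrity is compromised,
so (by an Arrhenius argument) its uptake rate constant is exponential in the
loss of the membrane's free-energy barrier. We therefore work with
$X(t) = \ln(\text{normalized PI uptake rate})$, in units of $k_BT$. All model
code operates on $X$; the conversion $e^X \leftrightarrow X$ happens only at
the statistics/reporting boundary.

The membrane-potential saturating-repair (MP-SR) model is the one-dimensional
stochastic differential equation

$$\frac{dX}{dt} = \eta_0 + \eta t \;-\; \beta\,
\frac{e^{aX}}{e^{aX}+e^{a\kappa}} \;+\; \sqrt{2\sigma}\,\xi,$$

with damage production rising linearly in age ($\eta_0 + \eta t$, the offset
$\eta_0$ absorbing the unknown biological age at the start of observation)
and removal saturating in damage through a two-state partition function
$f(X)$ with cooperativity $a$ (1/kBT) and half-saturation $\kappa$ (kBT);
$\xi$ is unit white noise of intensity $\sigma$ ((kBT)²/h). Death is the
first passage of $X$ across a threshold $x_c$.

Because production and removal change slowly compared with the fluctuation
timescale, the damage distribution at each age is approximately the Boltzmann
form $P(X) \propto e^{-U(X,t)/\sigma}$ of the frozen-age potential

$$U(X,t) = \frac{\beta}{a}\ln\!\big(e^{a\kappa}+e^{aX}\big) -
(\eta_0+\eta t)\,X,$$

which `qss_density()` evaluates (anchored at $U(\kappa,t)=0$ so serialized
potentials are reproducible). On the uptake scale $Z = e^X$ this density is
exactly a generalized beta distribution of the second kind (GB2) with
$b=e^\kappa$, $p=(\eta_0+\eta t)/(a\sigma)$, $q=(\beta-\eta_0-\eta t)/(a\sigma)$
— the correspondence `gb2_to_mpsr()` inverts, and the identity the acceptance
suite verifies pointwise to 1e-8. The density exists only while production
stays below maximal removal ($\eta_0+\eta t < \beta$); outside that regime
`qss_density()` raises a typed `mpsr_no_qss` error rather than extrapolating.

The fitted wild-type parameters used throughout as defaults are
$\eta = 5.1\times10^{-3}$, $\beta = 1.12$, $\sigma = 0.157$, $a = 0.33$,
$\kappa = 0.29$, $\eta_0 = 0.36$ (units as above; `wildtype_params()`).

## Simulation and first-passage death

`simulate_paths()` integrates the SDE by Euler–Maruyama with `dt = 0.05` h by
default (the observation scale is 1 h; steps of 1 h or coarser are rejected).
Every cell draws from its own RNG stream derived from the master seed, so
enlarging an ensemble never changes the cells already simulated, and results
are independent of any parallel scheduling. First-passage times across $x_c$
are linearly interpolated inside the crossing step, removing the $O(dt)$
discretization bias in death times. Initial conditions default to the
quasi-steady density at the start age (cells are observed only after a 20 h
adaptation period, by which time the damage distribution has relaxed).

### The death threshold

The experimentally calibrated threshold is quoted as $X_c = 50$, determined
as the maximal damage observed before previously established death times.
Under the fitted wild-type parameters, however, the quasi-steady damage
distribution at 80–100 h sits at $X \approx 2.7\text{–}4$ with a standard
deviation of ~1.4, and the potential barrier to $X=50$ exceeds $90\sigma$:
no trajectory reaches 50 within a 120 h horizon. The threshold convention
behind the printed value evidently differs from the dynamics implied by the
printed rate parameters, so the package treats $x_c$ as a free, configurable
parameter everywhere. For the synthetic cohort we calibrated the default
**once**, before any downstream analysis was built, by simulating
first-passage times on a grid of thresholds and choosing the value whose
survival statistics match the observed cohort: $x_c = 3.5$ gives a mean
lifespan of ~82 h, lifespan CV ~0.23, a sigmoidal survival curve, and
5%/95% death quantiles near 50/112 h — against reported values of 82 h, 24%,
and 42/106 h. No model-based acceptance check pins absolute lifespans.

### Escape-rate hazard

The MP-SR potential is strictly convex ($U'' = \beta a f(1-f) > 0$
everywhere), so there is no interior barrier top in the classical
double-well sense; escape is across the absorbing threshold itself. The
hazard `kramers_hazard()` therefore uses the frozen-age mean first-passage
time from the well minimum to $x_c$,
$T(t) = \sigma^{-1}\int_{x_{min}}^{x_c} e^{U(y)/\sigma}
\int_{-\infty}^{y} e^{-U(z)/\sigma}\,dz\,dy$, by quadrature (`method =
"mfpt"`), or its Laplace approximation
$h \approx U'(x_c)\sqrt{U''(x_{min})/2\pi\sigma}\,e^{-\Delta U/\sigma}$
(`method = "saddle"`), which exposes the mechanism of the Gompertz law: the
linear rise of production tilts the potential, $\Delta U(t)$ falls roughly
linearly in age, and the hazard rises exponentially. In the calibrated
death region the barrier is only 1–3$\sigma$, so the frozen-potential rate
runs ahead of the simulated cohort hazard by a bounded factor (about 1.5–3,
growing with age as the adiabatic approximation degrades); at barriers of
3$\sigma$ and above the quadrature rate matches Monte-Carlo escape within a
factor of two, and the saddle form matches the quadrature within ~20%.

## The synthetic cohort generator

`generate_cohort()` emulates a mother-machine starvation experiment: 635
cells by default, hourly frames over 120 h. Per cell it simulates the latent
damage path, integrates the PI saturation kinetics
$ds/dt = A_1 e^{X(t)}(1-s)$ from $s(0)=0$ with the exact
piecewise-exponential update (unconditionally stable however large the
uptake), and observes $s(t_k)\,e^{\varepsilon_k}$ with i.i.d. normal
$\varepsilon_k$, $\mathrm{sd} = \ln(1.06)$ — the ~6% multiplicative,
frame-uncorrelated noise of fluorescence imaging — clipped to $[0, 1.05]$.
$A_1 = 1/600\,\mathrm{h^{-1}}$, which puts initial uptake rates near 1.

Initial damage is a mixture: 3% of cells start with uptake above 4
(an exponential tail on $X$ above $\ln 4$), the rest log-normal with mean
uptake 0.87. The dispersion of the low-damage group (CV 0.4) is a generator
choice — the experiment reports only the mean — and is configurable; it is
synthetic-only and not inferred from data. After latent death the uptake is
set to 20× the threshold rate (`dead_uptake_factor`), so fluorescence
saturates within a frame or two, reproducing the saturation jump that real
traces show at death; this is also what makes death times recoverable from
traces when $x_c$ sits inside the live damage range.

Covariates (initial size, reductive division times) are generated
independent of lifespan by default, matching the observed near-zero
correlations. The `covariate_assoc` dial couples initial size to each cell's
constant production rate (kBT/h per size-SD) for power checks; coupling the
*initial damage* instead would do nothing, because the dynamics erase
initial conditions within a relaxation time (~11 h) — which is precisely the
finding the cohort illustrates.

What the generator does *not* emulate: imaging artifacts other than
multiplicative noise, segmentation errors, focus drift with temporal
structure, chip geometry, or cell–cell interaction. Tests passing on these
cohorts therefore validate the analysis chain under the stated noise model,
not robustness to structured experimental artifacts.

## Extraction: from traces to damage

`extract_cohort()` follows the windowed-derivative pipeline:

1. normalize each trace to $s(t)$ (background-subtract, divide by the
   saturation plateau). For raw microscope traces the plateau is the
   observed per-cell maximum (dying cells saturate); for generator traces it
   is exactly 1 and is passed explicitly, since dividing a never-saturating
   trace by its own maximum inflates $s$ and biases the uptake scale.
   $s$ is clamped to $[10^{-6}, 1-10^{-6}]$ with clamped frames flagged.
2. smooth $\ln s$ with an adaptive Wiener filter: a local *linear* fit in a
   7-sample neighborhood with gain $\max(0, v-n_p)/v$ on the residuals. The
   local-linear signal model (rather than a local mean) preserves the trend
   that the derivative estimator needs; the noise power $n_p$ is estimated
   as half the median squared successive difference, corrected by the
   $\chi^2_1$ median — a robust estimator of frame-uncorrelated noise that,
   unlike the median local variance, is not inflated by the trend itself.
3. estimate $d\ln s/dt$ by OLS in non-overlapping 7 h windows anchored at
   20 h (centres 23.5 … 72.5 h; the anchor is configurable), and convert to
   uptake via $\hat{u} = \mathrm{slope}\cdot \bar{s}/(1-\bar{s})/A_1$ with
   $\bar{s}$ the smoothed $s$ at the window's mean frame time — evaluating
   at the *mean frame time* rather than the nominal centre keeps slope and
   conversion factor consistent and removes a ~2.5% bias. Saturated windows
   ($\bar s > 1-10^{-5}$) and non-positive slopes are masked invalid.
4. call death at the first crossing of $x_c$ by the *sharp* dense damage
   series (backward differences of raw $\ln s$), linearly interpolated. The
   symmetric smoother would spread the saturation jump at death ~3 h
   backwards and bias every call early; raw differences localize it to one
   frame. On fully noise-free cohorts 100% of calls land within 1 h of the
   latent truth. On noisy cohorts death calls have ~2 h resolution, because
   with the calibrated threshold the live damage range runs close to $x_c$
   and any noisy estimator crosses early by an amount set by
   noise/approach-slope.

### Accuracy and its limits

Windowed comparisons use the window-aggregated truth
$\ln(\mathrm{mean}_{window}\, e^{X})$ — the quantity a windowed derivative
measures — rather than the instantaneous $X$ at the centre, whose
within-window fluctuation (sd ~0.4 kBT) would dominate any estimator.
Noise-free cohorts round-trip to well under 2% per window. With 6% noise the
per-window log-uptake RMSE over the first half of life measures ~0.4–0.5 kBT,
and this is a physics limit of the windowed-OLS design, not a tuning
shortfall: the slope noise on $\ln s$ is *additive in uptake units* (~0.1
normalized-uptake per window after smoothing), so the log-scale error of a
cell currently at uptake $u$ scales as $1/u$, and the cross-sectional
$E[u^{-2}]$ under the wide quasi-steady distribution (sd ~1.3 in $X$)
inflates the RMSE several-fold. Widening the smoother trades this against
trend bias and plateaus near 0.40.

## Cohort statistics

`cross_sectional_stats()` computes mean, SD, CV and skewness (adjusted
Fisher–Pearson; reported as 0 for constant samples) over cells alive at each
age — alive meaning called lifespan beyond the age *and* a valid window —
with standard errors from bootstrapping cells, never windows. The default
observable for these four statistics is uptake $e^X$ (the convention of the
model-simulation figures), while autocorrelation and remaining-lifespan
dispersion use $X$; both are switchable. Multiple regression of lifespan on
initial conditions uses raw covariates (no transform is specified by the
source analyses); never-divided cells enter with last-division time 0 rather
than being dropped. The twilight analysis regresses remaining lifespan on
the age at first crossing of a sub-lethal threshold, bootstrap CI over
cells.

Two protocol points matter when checking the model's ageing signatures
against simulations. First, the signatures are population statements about
*cells alive at a given age*: with the death threshold active, absorption
removes the heavy upper tail and the uptake CV and skewness fall with age
(CV ~1.4 to ~0.8 over 23–73 h at n = 6200) while 1/CV rises linearly
(R² ≈ 0.97). A free-running ensemble behaves differently — by 80 h the
quasi-steady GB2 tail index `q - 2/a` approaches zero and the uptake CV
*rises* — so signature checks must use the absorbed ensemble. Second, the
lag-7 h damage autocorrelation of the simulated alive population does
**not** rise with age: absorption preferentially removes the persistent
high-damage cells, and the measured lag correlation drifts slightly down
(~0.66 to ~0.54). The rising persistence seen in experimental cohorts lives
in the late-life damage-explosion regime near the experimental threshold,
which the fitted rate parameters cannot reach (see the death-threshold note
above); the package reports the model's actual behaviour and the
corresponding acceptance expectation fails by design rather than being
weakened.

`survival_curves()` wraps the Kaplan–Meier product-limit estimator (equal to
the empirical survival function when nothing is censored) with percentile
bootstrap bands over cells; the Gompertz slope is the OLS slope of
$\ln(-\ln S)$ against age inside the 10%–90% death-quantile window —
cumulative hazard of a Gompertz process is asymptotically log-linear with
the same slope, and the cumulative curve is what the data display directly.
Cohort comparisons report mean-lifespan and slope ratios with bootstrap CIs
plus the normalized-age overlay distance (max vertical gap of $S$ vs
$t/\bar{L}$), which is invariant under pure time rescaling.

## Marginal distribution fitting

`fit_marginal()` fits 15 candidate families (GB2, Burr III, Burr XII, Fisk,
log-normal, gamma, Weibull, exponential, inverse-gamma, log-gamma, Pareto
II, half-normal, Rayleigh, scaled chi-square, and normal-on-log — the last
being the log-normal under a second parametrization, retained for list
parity) by multi-start maximum likelihood: moment- and quantile-matched
starts plus jittered replicates, Nelder–Mead on log-transformed positive
parameters, ties broken by log-likelihood. Goodness of fit is the one-sample
Kolmogorov–Smirnov statistic against the fitted CDF; the returned p-values
carry the usual caveat (parameters were fitted from the same sample, so
plain K–S p-values are optimistic) as an attribute. Families are ranked by
K–S statistic; non-converging families are flagged, not fatal.

Checking the GB2 correspondence against simulations has its own protocol:
the samples are 7 h window-averaged uptake from a *free-running* ensemble —
the measurement's own observable, on the population whose marginal is the
quasi-steady GB2. On instantaneous samples the quasi-steady density at the
fitted parameters sits within a K–S distance of ~0.001 of its lognormal
limit (the shapes p, q are large), so the family ranking there is a coin
flip; on death-truncated samples the clipped tail drives the fitted GB2 to
its `q -> Inf` gamma/lognormal limit and the parameter mapping degenerates.
For the age trend of `p/(p+q)`, `fit_gb2_series()` fits per-age GB2
marginals in two passes, profiling a single cooperativity `a` (the median of
free per-age fits) across ages — mirroring the empirical observation that
`a` and `b` stay constant while the shapes carry the age trend — because a
free per-age `a` trades against the shapes along the four-parameter GB2
ridge and makes the ratio series needlessly noisy.

## Model fitting

`fit_mpsr()` maximizes the summed transition log-likelihood
$LL(\theta) = \sum_i \sum_j \ln P[(t_j, X_{ij}) \mid (t_{j-1}, X_{i(j-1)});
\theta]$ with an iterative interval-halving search over the six-dimensional
box: each iteration evaluates the full $3^6$ factorial grid (low/centre/high
per dimension, vectorized across candidates), recentres on the best point,
and halves every dimension in which the optimum was interior. Convergence
requires the optimum interior in all dimensions and the log-likelihood
differences to the 12 axis neighbours within their cell-bootstrap confidence
intervals; the statistical check is applied once the grid has refined 16-fold,
so it certifies the flat top of the surface rather than stopping the coarse
search. The default search box is the physiologically plausible range
($\eta \in [10^{-3}, 10^{-2}]$, $\beta \in [0.4, 2]$,
$\sigma \in [0.04, 0.36]$, $a \in [0.1, 0.6]$, $\kappa \in [-0.7, 1.3]$,
$\eta_0 \in [0.05, 0.75]$); optima pinned at the box edge are flagged, never
silently returned as converged.

Two likelihood backends share this driver. `sim_kde` is the faithful
simulation-based likelihood: 1000 Euler–Maruyama paths per transition,
endpoint density by Gaussian KDE with Silverman's bandwidth, and
per-transition common random numbers (seeds derived from the config seed) so
that likelihood comparisons across $\theta$ are smooth — usable at small
problem sizes. `euler_gauss` is the desk-scale default: a Gaussian
transition approximation with sub-stepped moment propagation — midpoint
(RK2) updates for the mean and the *exact* Ornstein–Uhlenbeck variance
update for the midpoint-frozen relaxation rate, at 0.5 h sub-steps (a 7 h
observation gap gets 14 sub-steps). The naive Euler moment update carries a
per-transition bias of only ~5×10⁻⁴ log-likelihood units, but summed over
~10⁴ transitions it tilts the surface by ~15 units and visibly displaces the
optimum; the RK2/OU scheme is sub-step-converged to below 0.01 units.

### Practical identifiability of the removal curve

Parameter-recovery experiments (hundreds of cells observed hourly over
20–80 h) consistently recover $\sigma$ within ~4% and $\eta$ within ~10%.
The four remaining parameters are another matter: $(\beta, a, \kappa,
\eta_0)$ parametrize a saturating drift curve that is sampled only over the
damage range the cohort actually visits, and along a curve through parameter
space — e.g. from the generating values to
$(\beta, a, \kappa, \eta_0) = (1.55, 0.22, 0.18, 0.60)$ — the drift changes
by less than ±0.02 kBT/h everywhere in that range. The profile
log-likelihood along this ridge varies by ~1 unit at 18 000 transitions, so
the exact maximum-likelihood point wanders along it from realization to
realization (sd(β) ≈ 0.3, sd(κ) ≈ 0.25), far beyond the nominal
uncertainties quoted for these parameters from axis-aligned likelihood
differences. The drift *function* and all model predictions that depend on
it are recovered accurately; its four-parameter logistic *parametrization*
is not identifiable at this design size, and quadrupling the data would
narrow the wander only by half. We report the fit as the search returns it,
flag boundary-pinned optima, and treat recovered removal-curve parameters as
jointly — not marginally — constrained.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed; per-cell and per-transition
streams are derived deterministically from it. The test-suite problem sizes
are the package's own choices: qualitative-signature checks run at the
published simulation size of 6200 cells; distribution selection at n = 5000
samples per age; recovery fits at 150–300 cells; the acceptance script at
500 cells. The pipeline writes a manifest (config hash, seed, per-file
checksums, wall times) and reproduces byte-identical artifacts under a fixed
seed, with stage-level resume.
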