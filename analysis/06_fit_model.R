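#!/usr/bin/env Rscript
# Maximum-likelihood fit of the six MP-SR parameters to damage trajectories
# via the Gaussian transition likelihood and interval-halving grid search.
# Run on dense (hourly) latent damage generated from the published wild-type
# parameters: a parameter-recovery experiment. Fitting the noisy windowed
# extraction output instead is possible (pass results/extraction/windows.csv
# through transition_table) but is left out of the default run: 8 windows per
# cell carry little information per cell and measurement error biases sigma.

suppressMessages(library(mpsr))

dir.create("results/fit", showWarnings = FALSE, recursive = TRUE)
truth <- wildtype_params()
n <- 300
ens <- simulate_paths(truth, n = n, t0 = 20, t1 = 80, dt = 0.05, seed = 41)
hourly <- which(ens$times %% 1 == 0)
obs <- data.frame(cell_id = rep(sprintf("c%04d", 1:n), each = length(hourly)),
                  time_h = rep(ens$times[hourly], n),
                  damage_kBT = as.vector(t(ens$paths[, hourly])))
tr <- transition_table(obs)
message(sprintf("Fitting %d transitions from %d cells ...", nrow(tr), n))
fit <- fit_mpsr(tr, fit_config(seed = 42))
print(fit)
write_fit(fit, "results/fit/mpsr_fit.json")

est <- unlist(fit$theta_hat); tru <- unlist(truth)
for (nm in names(est))
  message(sprintf("  %6s: true %.4g  recovered %.4g  (%+.0f%%)",
                  nm, tru[nm], est[nm], 100 * (est[nm] / tru[nm] - 1)))
message("Note: beta, a, kappa and eta0 share a flat likelihood ridge at this",
        " problem size; sigma and eta are the precisely identified",
        " parameters. See the methods vignette.")
message("Wrote results/fit/mpsr_fit.json")
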