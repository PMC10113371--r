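# shared fixtures, built once per test run

wt <- wildtype_params()

# small damage-observation table sampled hourly from a simulated ensemble
make_damage_obs <- function(n = 50, t0 = 20, t1 = 60, seed = 1,
                            params = wt, every_h = 1) {
  ens <- simulate_paths(params, n = n, t0 = t0, t1 = t1, dt = 0.05,
                        seed = seed)
  idx <- which(abs(ens$times / every_h - round(ens$times / every_h)) < 1e-9)
  data.frame(cell_id = rep(sprintf("c%04d", seq_len(n)),
                           each = length(idx)),
             time_h = rep(ens$times[idx], n),
             damage_kBT = as.vector(t(ens$paths[, idx])))
}

# cached default synthetic cohort (150 cells) reused across test files
cohort_cache <- new.env(parent = emptyenv())
get_test_cohort <- function(noise_cv = 0.06, n_cells = 150, seed = 7) {
  key <- sprintf("c_%g_%d_%d", noise_cv, n_cells, seed)
  if (is.null(cohort_cache[[key]])) {
    cfg <- cohort_config(n_cells = n_cells, noise_cv = noise_cv, seed = seed)
    cohort_cache[[key]] <- list(config = cfg, cohort = generate_cohort(cfg))
  }
  cohort_cache[[key]]
}
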