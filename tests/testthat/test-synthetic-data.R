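test_that("constant-damage noiseless cohort reproduces the closed-form trace", {
  # X = ln 2 frozen -> s(t) = 1 - exp(-2 t / 600); extraction recovers
  # uptake 2 at every interior window
  p <- mpsr_params(eta0 = 1.12 * stats::plogis(0.33 * (log(2) - 0.29)),
                   eta = 0, beta = 1.12, sigma = 1e-14, a = 0.33,
                   kappa = 0.29)
  cfg <- cohort_config(n_cells = 3, params = p, noise_cv = 0,
                       high_damage_fraction = 0, baseline_uptake_mean = 2,
                       baseline_uptake_cv = 0, seed = 2)
  ch <- generate_cohort(cfg)
  tr1 <- ch$traces[ch$traces$cell_id == "cell_0001", ]
  x0 <- ch$truth$x0[1]
  expect_equal(tr1$fluorescence,
               1 - exp(-exp(x0) * tr1$time_h / 600), tolerance = 1e-5)
  ex <- extract_cohort(ch$traces, cfg$rule)
  w <- ex$windows[ex$windows$cell_id == "cell_0001" & ex$windows$valid, ]
  expect_true(all(abs(w$uptake / exp(x0) - 1) < 0.02))
})

test_that("high-damage subpopulation matches its configured frequency", {
  cc <- get_test_cohort(noise_cv = 0, n_cells = 635, seed = 21)
  u0 <- cc$cohort$covariates$initial_uptake
  n_hi <- sum(u0 > 4)
  # binomial 99% interval around 3% of 635
  expect_gte(n_hi, stats::qbinom(0.005, 635, 0.03))
  expect_lte(n_hi, stats::qbinom(0.995, 635, 0.03))
  expect_true(all(u0[cc$cohort$covariates$high_damage] >= 4))
  # mean of the low-damage group near the configured 0.87
  expect_equal(mean(u0[u0 < 4]), 0.87, tolerance = 0.1)
  # degenerate mixture: no cell above threshold
  cfg0 <- cohort_config(n_cells = 300, high_damage_fraction = 0, seed = 3)
  ch0 <- generate_cohort(cfg0)
  expect_lt(max(ch0$covariates$initial_uptake), 4)
})

test_that("log-fluorescence increments are uncorrelated under 6% noise", {
  cc <- get_test_cohort()
  ch <- cc$cohort
  # pick long-lived cells, pool increment pairs over frames 5..60
  rs <- c()
  for (id in ch$covariates$cell_id[which(is.na(ch$truth$lifespan_h))][1:20]) {
    f <- ch$traces$fluorescence[ch$traces$cell_id == id]
    d <- diff(log(pmax(f[5:61], 1e-8)))
    rs <- c(rs, suppressWarnings(stats::cor(d[-1], d[-length(d)])))
  }
  # noise is frame-uncorrelated: pooled increment autocorrelation stays
  # near zero (smooth-signal trends and differenced white noise pull in
  # opposite directions, neither dominating)
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
})

test_that("noise-free extraction recovers latent lifespans within one frame", {
  cc <- get_test_cohort(noise_cv = 0)
  ex <- extract_cohort(cc$cohort$traces, cc$config$rule)
  tl <- cc$cohort$truth$lifespan_h
  el <- ex$lifespans$lifespan_h
  ok <- !is.na(tl) & !is.na(el)
  expect_gt(sum(ok), 100)
  expect_gte(mean(abs(el[ok] - tl[ok]) <= 1), 0.99)
})

test_that("generated survival is sigmoidal with a rising hazard", {
  cc <- get_test_cohort(noise_cv = 0, n_cells = 635, seed = 21)
  L <- cc$cohort$truth$lifespan_h
  d <- L[!is.na(L)]
  expect_gt(length(d), 500)
  # deaths concentrated at intermediate ages: few early, few at horizon
  expect_lt(mean(d < 40), 0.1)
  expect_gt(mean(d > 60 & d < 110), 0.5)
  # empirical cumulative hazard convex (rising hazard): late-age increments
  # exceed early-age increments
  sc <- survival_curves(L, n_boot = 50, seed = 1)
  ch_at <- function(t) with(sc$curve, cumhaz[findInterval(t, time_h)])
  expect_gt(ch_at(100) - ch_at(85), ch_at(70) - ch_at(55))
})

test_that("cohort files round-trip through write_truth/read_cohort", {
  cfg <- cohort_config(n_cells = 12, horizon_h = 120, seed = 4)
  ch <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_truth(ch, dir)
  expect_error(write_truth(ch, dir), "overwrite")
  back <- read_cohort(dir)
  expect_equal(back$traces$fluorescence, ch$traces$fluorescence)
  expect_equal(nrow(back$covariates), 12)
  expect_equal(unlist(back$truth$params), unlist(cfg$params))
  expect_equal(back$truth$rule$x_c, cfg$rule$x_c)
  expect_equal(as.numeric(back$truth$cells$lifespan_h),
               as.numeric(ch$truth$lifespan_h))
})

test_that("covariate association dial induces a lifespan correlation", {
  cfg <- cohort_config(n_cells = 250, covariate_assoc = 0.04, noise_cv = 0,
                       seed = 9)
  ch <- generate_cohort(cfg)
  ok <- !is.na(ch$truth$lifespan_h)
  r <- stats::cor(ch$covariates$initial_size_um[ok],
                  ch$truth$lifespan_h[ok], method = "spearman")
  expect_gt(r, 0.2)  # larger cells got less initial damage -> live longer
  # and the default is no association
  cc0 <- get_test_cohort(noise_cv = 0)
  ok0 <- !is.na(cc0$cohort$truth$lifespan_h)
  r0 <- stats::cor(cc0$cohort$covariates$initial_size_um[ok0],
                   cc0$cohort$truth$lifespan_h[ok0], method = "spearman")
  expect_lt(abs(r0), 0.2)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(frame_interval_h = 0.7), "divide")
  expect_error(cohort_config(noise_cv = -0.1), "noise_cv")
  expect_error(cohort_config(a1 = 0), "a1")
  expect_error(cohort_config(high_damage_fraction = 1.2), "fraction")
})
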