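test_that("normalization is invariant to gain and offset", {
  t <- 0:119
  s <- 1 - exp(-t / 300)
  raw <- 850 * s + 40  # gain 850, offset 40
  nrm1 <- normalize_series(t, raw, background = 40)
  nrm2 <- normalize_series(t, s, background = 0)
  expect_equal(nrm1$s, nrm2$s, tolerance = 1e-12)
  # default background: mean of first three frames
  nrm3 <- normalize_series(t, s + 0.002, background = NULL)
  expect_equal(mean((s + 0.002)[1:3]) ,  0.002 + mean(s[1:3]))
  expect_true(all(nrm3$s <= 1))
})

test_that("degenerate series are flagged or rejected", {
  t <- 0:30
  expect_error(normalize_series(t, rep(5, 31), background = 5), "flat")
  expect_error(normalize_series(0:5, rep(1, 6)), "10 frames")
  spike <- c(rep(0, 15), 1, rep(0, 15))
  nrm <- normalize_series(t, spike, background = 0)
  expect_true(all(nrm$s >= 1e-6 & nrm$s <= 1 - 1e-6))
  expect_true(all(nrm$clamped[spike == 0]))
})

test_that("windowed uptake recovers constant-rate closed forms", {
  t <- 0:120
  for (lam in c(1, 2)) {
    s <- 1 - exp(-lam * t / 600)
    tr <- estimate_uptake(normalize_series(t, s, background = 0,
                                           saturation = 1))
    w <- tr$uptake[tr$valid][1:8]
    expect_true(all(abs(w / lam - 1) < 0.02))
  }
  # doubling the rate doubles the estimate (small-s linearity)
  s1 <- 1 - exp(-1 * t / 600); s2 <- 1 - exp(-2 * t / 600)
  u1 <- estimate_uptake(normalize_series(t, s1, 0, 1))$uptake[1]
  u2 <- estimate_uptake(normalize_series(t, s2, 0, 1))$uptake[1]
  expect_equal(u2 / u1, 2, tolerance = 0.05)
})

test_that("uptake estimation is time-shift equivariant", {
  t <- 0:120
  s <- 1 - exp(-1.5 * t / 600)
  base <- estimate_uptake(normalize_series(t, s, 0, 1))
  shifted <- estimate_uptake(normalize_series(t + 14, s, 0, 1))
  # same fluorescence course started 14 h (2 windows) later: window k of the
  # shifted series sees the data window k-2 saw
  expect_equal(shifted$uptake[1:6], base$uptake[1:6], tolerance = 0.03)
})

test_that("saturated and non-positive-slope windows are masked", {
  t <- 0:80
  s <- c(seq(0.001, 0.9995, length.out = 41), rep(0.9995, 40))
  tr <- estimate_uptake(normalize_series(t, s, 0, 1))
  expect_true(any(!tr$valid))
  # a fully saturated tail yields a typed empty result, not an exception
  s2 <- rep(0.99999, 81)
  tr2 <- estimate_uptake(normalize_series(t, pmin(s2, 1 - 1e-6), 0, 1))
  expect_true(tr2$empty)
})

test_that("death calling interpolates threshold crossings", {
  # synthetic dense damage crossing x_c = 3 exactly halfway between frames
  traj <- list(times = 0:10,
               dense_damage_raw = c(0, 0.5, 1, 1.5, 2, 2.5, 2.8, 3.2, 4, 5, 6))
  d <- call_death(traj, death_rule(3))
  expect_false(d$censored)
  expect_equal(d$lifespan_h, 6 + (3 - 2.8) / (3.2 - 2.8))
  # never crossing -> censored at horizon
  traj2 <- list(times = 0:10, dense_damage_raw = rep(1, 11))
  d2 <- call_death(traj2, death_rule(3))
  expect_true(d2$censored)
  expect_equal(d2$horizon, 10)
})

test_that("threshold calibration returns the maximal pre-death damage", {
  trajs <- list(
    a = list(times = 0:10, dense_damage = c(0:6, 7, 8, 9, 10),
             dense_damage_raw = c(0:6, 7, 8, 9, 10)),
    b = list(times = 0:10, dense_damage = seq(0, 5, length.out = 11),
             dense_damage_raw = seq(0, 5, length.out = 11)))
  # cell a died at 8 h (max pre-death damage 7), cell b censored (max 5)
  xc <- calibrate_threshold(trajs, c(8, NA))
  expect_equal(xc, 7)
})

test_that("noise-free cohort round trip meets the accuracy targets", {
  # fully noise-free: measurement noise off and deterministic latent paths
  p <- wildtype_params()
  p0 <- mpsr_params(eta0 = p$eta0, eta = p$eta, beta = p$beta, sigma = 1e-14,
                    a = p$a, kappa = p$kappa)
  cfg <- cohort_config(n_cells = 80, params = p0, noise_cv = 0, seed = 5)
  ch <- generate_cohort(cfg)
  ex <- extract_cohort(ch$traces, cfg$rule)
  tw <- truth_windowed_damage(ch)
  m <- merge(ex$windows[ex$windows$valid, ], tw,
             by = c("cell_id", "window_center_h"))
  rel <- abs(exp(m$damage_kBT - m$truth_damage) - 1)
  expect_gte(mean(rel < 0.02), 0.99)
  tl <- ch$truth$lifespan_h; el <- ex$lifespans$lifespan_h
  ok <- !is.na(tl) & !is.na(el)
  expect_gte(mean(abs(el[ok] - tl[ok]) <= 1), 0.99)
})

test_that("initial windows average near uptake 1 under baseline initial damage", {
  cc <- get_test_cohort(noise_cv = 0)
  ex <- extract_cohort(cc$cohort$traces, cc$config$rule)
  alive <- ex$lifespans$cell_id[is.na(ex$lifespans$lifespan_h) |
                                  ex$lifespans$lifespan_h > 23.5]
  w1 <- ex$windows[ex$windows$window_center_h == 23.5 & ex$windows$valid &
                     ex$windows$cell_id %in% alive, ]
  # calibration property of A1: first-window uptake starts close to 1
  # (within a factor of 2; the quasi-steady spread is wide)
  expect_lt(abs(log(mean(w1$uptake))), log(2))
})
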