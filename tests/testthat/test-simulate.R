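test_that("zero-noise simulation matches a high-order ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- mpsr_params(eta0 = 0.36, eta = 5.1e-3, beta = 1.12, sigma = 1e-14,
                   a = 0.33, kappa = 0.29)
  ens <- simulate_paths(p, x0_sampler = 0.5, t0 = 20, t1 = 60, dt = 0.01,
                        n = 1, seed = 1)
  ode <- deSolve::ode(y = c(x = 0.5), times = ens$times,
                      func = function(t, y, parms)
                        list(mpsr_drift(y, t, p)),
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  # Euler's global error at dt = 0.01 dominates the comparison
  expect_lt(max(abs(ens$paths[1, ] - ode[, "x"])), 5e-4)
})

test_that("no-removal, no-noise paths follow the closed-form integral", {
  p <- mpsr_params(eta0 = 0.2, eta = 4e-3, beta = 1e-12, sigma = 1e-14,
                   a = 0.33, kappa = 0.29)
  ens <- simulate_paths(p, x0_sampler = 1.5, t0 = 10, t1 = 50, dt = 0.05,
                        n = 1, seed = 1)
  tt <- ens$times
  # the discrete left-endpoint sum is matched exactly ...
  discrete <- 1.5 + c(0, cumsum((0.2 + 4e-3 * tt[-length(tt)]) * 0.05))
  expect_equal(ens$paths[1, ], discrete, tolerance = 1e-6)
  # ... and the continuous closed form up to O(dt) quadrature error
  closed <- 1.5 + 0.2 * (tt - 10) + 4e-3 * (tt^2 - 100) / 2
  expect_equal(ens$paths[1, ], closed, tolerance = 5e-3)
})

test_that("per-cell RNG streams make paths independent of ensemble size", {
  p <- wildtype_params()
  e10 <- simulate_paths(p, n = 10, t0 = 20, t1 = 30, dt = 0.05, seed = 5)
  e25 <- simulate_paths(p, n = 25, t0 = 20, t1 = 30, dt = 0.05, seed = 5)
  expect_identical(e10$paths, e25$paths[1:10, ])
  # and fully reproducible under the same seed
  e10b <- simulate_paths(p, n = 10, t0 = 20, t1 = 30, dt = 0.05, seed = 5)
  expect_identical(e10$paths, e10b$paths)
  expect_error(simulate_paths(p, n = 10, dt = 1.5), "dt")
})

test_that("frozen-age long-run ensemble matches the quasi-steady density", {
  p <- wildtype_params()
  frozen <- mpsr_params(eta0 = p$eta0 + p$eta * 50, eta = 0, beta = p$beta,
                        sigma = p$sigma, a = p$a, kappa = p$kappa)
  ens <- simulate_paths(frozen, n = 10000, t0 = 0, t1 = 60, dt = 0.05,
                        seed = 8)
  x_end <- ens$paths[, ncol(ens$paths)]
  q <- qss_density(0, frozen)
  dx <- diff(q$x)
  cdf <- cumsum(c(0, dx * (q$density[-1] + q$density[-length(q$density)]) / 2))
  cdf <- pmin(cdf / max(cdf), 1)
  theo_cdf <- stats::approxfun(q$x, cdf, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(x_end, theo_cdf))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("ballistic and drifted-Brownian first passage match closed forms", {
  # ballistic: dX = eta0 dt from 0 to x_c = 10 at eta0 = 1 -> 10 h
  p_ball <- mpsr_params(eta0 = 1, eta = 0, beta = 1e-12, sigma = 1e-12,
                        a = 0.33, kappa = 0.29)
  fps <- sample_first_passage(p_ball, death_rule(10), x0_sampler = 0,
                              t0 = 0, horizon = 40, dt = 0.05, n = 50,
                              seed = 2)
  expect_equal(mean(fps$death_times), 10, tolerance = 1e-2)
  expect_identical(fps$censored, 0L)
  # drifted Brownian: E[T] = (x_c - x0)/eta0 (Wald identity)
  p_bm <- mpsr_params(eta0 = 1, eta = 0, beta = 1e-12, sigma = 0.5,
                      a = 0.33, kappa = 0.29)
  fps2 <- sample_first_passage(p_bm, death_rule(10), x0_sampler = 0,
                               t0 = 0, horizon = 200, dt = 0.02, n = 1500,
                               seed = 3)
  expect_identical(fps2$censored, 0L)
  se <- stats::sd(fps2$death_times) / sqrt(length(fps2$death_times))
  expect_lt(abs(mean(fps2$death_times) - 10), 4 * se + 0.05)
})

test_that("zero absorbed cells warn and hazard estimation refuses", {
  p <- wildtype_params()  # x_c = 50 unreachable in 30 h
  expect_warning(
    fps <- sample_first_passage(p, death_rule(50), t0 = 20, horizon = 50,
                                dt = 0.05, n = 20, seed = 1),
    "zero cells absorbed")
  expect_error(empirical_hazard(fps), "no deaths")
})

test_that("escape-rate hazard rises with age and is log-linear in the barrier regime", {
  p <- wildtype_params()
  rule <- death_rule(3.5)
  ts <- seq(30, 85, by = 5)  # the well minimum passes x_c near 92 h
  h <- kramers_hazard(p, rule, ts)
  expect_true(all(diff(h) > 0))
  # ln hazard approximately linear in age where the barrier shrinks linearly
  fit <- stats::lm(log(h) ~ ts)
  expect_gt(summary(fit)$r.squared, 0.95)
  # saddle form agrees with the quadrature form while the barrier is still
  # a few sigma (it decays to ~1 sigma by mid-life, where Laplace
  # asymptotics give way)
  early <- ts <= 45
  h_saddle <- kramers_hazard(p, rule, ts, method = "saddle")
  expect_true(all(h_saddle[early] / h[early] > 0.67 &
                    h_saddle[early] / h[early] < 1.5))
  # beyond the regime: non-confining age or well minimum above threshold
  t_bad <- (p$beta - p$eta0) / p$eta + 1
  expect_error(kramers_hazard(p, rule, t_bad), class = "mpsr_no_barrier")
  expect_error(kramers_hazard(p, death_rule(0.1), 100),
               class = "mpsr_no_barrier")
})

test_that("escape rate matches simulation within a factor of 2 at a high barrier", {
  # frozen-age escape problem with a ~3.5 sigma barrier: the mean
  # first-passage time from quadrature must match Monte-Carlo escape times
  p50 <- mpsr_params(eta0 = 0.615, eta = 0, beta = 1.12, sigma = 0.157,
                     a = 0.33, kappa = 0.29)
  rule <- death_rule(4.6)
  q <- qss_density(0, p50)
  barrier <- (mpsr_potential(rule$x_c, 0, p50) -
                mpsr_potential(q$x_star, 0, p50)) / p50$sigma
  expect_gt(barrier, 3)
  rate <- kramers_hazard(p50, rule, 0)
  fps <- sample_first_passage(p50, rule, x0_sampler = q$x_star, t0 = 0,
                              horizon = 6 / rate, dt = 0.1, n = 200,
                              seed = 13)
  expect_gt(length(fps$death_times), 150)
  # censored-aware mean via the exponential escape rate
  total_time <- sum(fps$death_times) +
    fps$censored * (6 / rate)
  emp_rate <- length(fps$death_times) / total_time
  expect_gt(rate / emp_rate, 0.5)
  expect_lt(rate / emp_rate, 2)
})

test_that("frozen-potential escape rate brackets the ageing-cohort hazard", {
  # in the ageing cohort the barrier is only 1-3 sigma and the instantaneous
  # escape rate runs ahead of the adiabatically lagging empirical hazard by
  # a bounded factor
  p <- wildtype_params()
  rule <- death_rule(3.5)
  fps <- sample_first_passage(p, rule, t0 = 20, horizon = 120, dt = 0.05,
                              n = 2000, seed = 13)
  eh <- empirical_hazard(fps, bin_h = 5)
  sel <- eh$deaths >= 20 & eh$at_risk > 100 & eh$age_h <= 80
  ratio <- kramers_hazard(p, rule, eh$age_h[sel]) / eh$hazard[sel]
  expect_true(all(ratio > 0.8 & ratio < 3))
})
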